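test_that("density rules reproduce their hand-evaluated spot values", {
  comps <- list(tiny_component("A", c(1, 2), c(1, 0), true_density = 1.0,
                               bulk_density = 0.4),
                tiny_component("B", c(1, 2), c(0, 1), true_density = 2.0,
                               bulk_density = 0.6))
  f <- formulation("B", c("A", "B"), c(0.5, 0.5))
  expect_equal(mix_true_density(f, comps, "harmonic"), 4 / 3, tolerance = 1e-15)
  expect_equal(mix_true_density(f, comps, "arithmetic"), 1.5, tolerance = 1e-15)
  expect_equal(mix_true_density(f, comps, "geometric"), sqrt(2), tolerance = 1e-15)
  expect_equal(mix_bulk_density(f, comps, "mass_weighted"), 0.5, tolerance = 1e-15)
  # the two weighted bulk alternates, evaluated by hand:
  # mass+true-density:  (0.5*1*0.4 + 0.5*2*0.6) / (0.5*1 + 0.5*2) = 0.8/1.5
  expect_equal(mix_bulk_density(f, comps, "mass_true_density_weighted"),
               0.8 / 1.5, tolerance = 1e-15)
  # particle-volume:   (0.5*0.4/1 + 0.5*0.6/2) / (0.5/1 + 0.5/2) = 0.35/0.75
  expect_equal(mix_bulk_density(f, comps, "particle_volume_weighted"),
               0.35 / 0.75, tolerance = 1e-15)
})

test_that("pure formulations return the component density under every rule", {
  comps <- random_components(2, seed = 5)
  f <- formulation("P", "C1", 1)
  for (r in c("harmonic", "arithmetic", "geometric")) {
    expect_equal(mix_true_density(f, comps, r), comps[[1]]$true_density)
  }
  for (r in c("mass_weighted", "mass_true_density_weighted",
              "particle_volume_weighted")) {
    expect_equal(mix_bulk_density(f, comps, r), comps[[1]]$bulk_density)
  }
})

test_that("harmonic <= geometric <= arithmetic and all rules stay in the density envelope", {
  set.seed(17)
  comps <- random_components(5, seed = 17)
  rho <- vapply(comps, `[[`, 0, "true_density")
  for (i in 1:200) {
    f <- random_formulation(comps, sprintf("D%d", i))
    h <- mix_true_density(f, comps, "harmonic")
    g <- mix_true_density(f, comps, "geometric")
    a <- mix_true_density(f, comps, "arithmetic")
    expect_true(h <= g + 1e-12 && g <= a + 1e-12)
    sel <- rho[match(f$component_abbrs,
                     vapply(comps, `[[`, "", "abbreviation"))]
    sel <- sel[f$mass_fractions > 0]
    expect_true(h >= min(sel) - 1e-12 && a <= max(sel) + 1e-12)
  }
})

test_that("bulk rules coincide when all true densities are equal", {
  comps <- list(tiny_component("A", c(1, 2), c(1, 0), true_density = 1.5,
                               bulk_density = 0.4),
                tiny_component("B", c(1, 2), c(0, 1), true_density = 1.5,
                               bulk_density = 0.7))
  f <- formulation("B", c("A", "B"), c(0.3, 0.7))
  vals <- vapply(c("mass_weighted", "mass_true_density_weighted",
                   "particle_volume_weighted"),
                 function(r) mix_bulk_density(f, comps, r), 0)
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-15)
})

test_that("rule comparison metrics behave as closed forms dictate", {
  measured <- c(1.2, 1.4, 1.6, 1.8)
  perfect <- compare_density_rules(list(exact = measured), measured)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)

  shifted <- compare_density_rules(list(off = measured + 0.07), measured)
  expect_equal(shifted$rmse, 0.07, tolerance = 1e-12)

  expect_warning(
    out <- compare_density_rules(list(r = c(1, 1.1)), c(1.5, 1.5)),
    "constant")
  expect_true(is.nan(out$r_squared))
})

test_that("the generating rule attains zero RMSE on a synthetic blend set", {
  comps <- random_components(4, seed = 23)
  set.seed(23)
  forms <- lapply(1:20, function(i) random_formulation(comps, sprintf("S%d", i)))
  measured <- vapply(forms, function(f) mix_true_density(f, comps, "harmonic"), 0)
  preds <- lapply(c(harmonic = "harmonic", arithmetic = "arithmetic",
                    geometric = "geometric"), function(r) {
    vapply(forms, function(f) mix_true_density(f, comps, r), 0)
  })
  tab <- compare_density_rules(preds, measured)
  expect_equal(tab$rule[1], "harmonic")
  expect_equal(tab$rmse[tab$rule == "harmonic"], 0, tolerance = 1e-14)
  expect_true(all(tab$rmse >= 0))
})
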