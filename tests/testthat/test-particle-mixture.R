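test_that("membership weights reproduce the hand-evaluated single-class case", {
  comps <- single_class_pair()
  f <- formulation("B", c("A", "B"), c(0.5, 0.5))
  w <- membership_weights(f, comps)
  # equal mass, density, shape: the 1-um powder holds 1/1^3 : 1/2^3 = 8 : 1
  expect_equal(w$lambdas, c(8 / 9, 1 / 9), tolerance = 1e-15)
  expect_equal(sum(w$lambdas), 1, tolerance = 1e-12)
})

test_that("membership weights are trivial for pure blends and symmetric inputs", {
  comps <- random_components(3, seed = 2)
  pure <- formulation("P", "C1", 1)
  expect_equal(membership_weights(pure, comps)$lambdas, 1)

  # identical components in every respect -> equal weights
  twin <- comps[c(1, 1)]
  twin[[2]]$abbreviation <- "C1b"
  f <- formulation("T", c("C1", "C1b"), c(0.5, 0.5))
  expect_equal(membership_weights(f, twin)$lambdas, c(0.5, 0.5))
})

test_that("frequency-weighted size term matches its independent hand oracle", {
  g <- c(1, 2)
  compA <- tiny_component("A", g, c(0.5, 0.5))
  compB <- tiny_component("B", g, c(0.25, 0.75))
  f <- formulation("B", c("A", "B"), c(0.5, 0.5))
  # printed form: S_j = sum 1/d^3 is identical for both -> equal weights
  expect_equal(membership_weights(f, list(compA, compB))$lambdas, c(0.5, 0.5))
  # variant: S_j = sum n_ji/d^3, evaluated independently here
  sA <- 0.5 / 1 + 0.5 / 8
  sB <- 0.25 / 1 + 0.75 / 8
  expect_equal(
    membership_weights(f, list(compA, compB),
                       use_frequency_weighting = TRUE)$lambdas,
    c(sA, sB) / (sA + sB), tolerance = 1e-15)
})

test_that("size mixing matches the hand case and keeps convexity invariants", {
  comps <- single_class_pair()
  f <- formulation("B", c("A", "B"), c(0.5, 0.5))
  mix <- mix_size_distribution(f, comps)
  expect_equal(mix$frequencies, c(8 / 9, 1 / 9), tolerance = 1e-15)

  set.seed(13)
  comps <- random_components(4, seed = 13)
  for (i in 1:20) {
    fm <- random_formulation(comps, sprintf("R%d", i))
    m <- mix_size_distribution(fm, comps)
    expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
    sel <- lapply(fm$component_abbrs, function(a) {
      comps[[which(vapply(comps, `[[`, "", "abbreviation") == a)]]
    })
    freqs <- do.call(rbind, lapply(sel, function(cc) cc$psd$frequencies))
    # convexity: each mixed class lies within the component envelope
    expect_true(all(m$frequencies >= apply(freqs, 2, min) - 1e-12))
    expect_true(all(m$frequencies <= apply(freqs, 2, max) + 1e-12))
  }
})

test_that("pure formulations return the component distribution bit-exactly", {
  comps <- random_components(3, seed = 31)
  f <- formulation("P", "C2", 1)
  expect_identical(mix_size_distribution(f, comps)$frequencies,
                   comps[[2]]$psd$frequencies)
  expect_identical(mix_shape_distribution(f, comps)$frequencies,
                   comps[[2]]$ard$frequencies)
})

test_that("shape mixing weighs by mass over true density, normalized", {
  arg <- class_grid(c(0.25, 0.5, 0.75), "aspect_ratio")
  mk <- function(abbr, rho, ard_f) {
    cc <- tiny_component(abbr, c(1, 2), c(0.5, 0.5), true_density = rho,
                         bulk_density = 0.3)
    cc$ard <- freq_dist(arg, ard_f)
    cc
  }
  a <- mk("A", 1.5, c(1, 0, 0))
  b <- mk("B", 0.5, c(0, 0, 1))
  # C/rho: 0.75/1.5 = 0.25/0.5 -> equal weights
  f <- formulation("B", c("A", "B"), c(0.75, 0.25))
  m <- mix_shape_distribution(f, list(a, b))
  expect_equal(m$frequencies, c(0.5, 0, 0.5), tolerance = 1e-15)
  expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)

  # equal mass and density -> plain average
  f2 <- formulation("B2", c("A", "B"), c(0.5, 0.5))
  b2 <- mk("B2c", 1.5, c(0, 1, 0)); b2$abbreviation <- "B"
  m2 <- mix_shape_distribution(f2, list(a, b2))
  expect_equal(m2$frequencies, c(0.5, 0.5, 0) / 1, tolerance = 1e-15)
})

test_that("the weighted-average percentile baseline averages component percentiles", {
  a <- tiny_component("A", c(5, 10, 20), c(0, 1, 0))
  b <- tiny_component("B", c(5, 20, 40), c(0, 1, 0))
  f <- formulation("B", c("A", "B"), c(0.5, 0.5))
  expect_equal(baseline_percentile_mixture(f, list(a, b), 0.5), 15)
  pure <- formulation("P", "A", 1)
  expect_equal(baseline_percentile_mixture(pure, list(a, b), 0.5), 10)
})

test_that("mismatched grids are refused with a pointer to regrid", {
  a <- tiny_component("A", c(1, 2), c(0.5, 0.5))
  b <- tiny_component("B", c(1, 3), c(0.5, 0.5))
  f <- formulation("B", c("A", "B"), c(0.5, 0.5))
  expect_error(mix_size_distribution(f, list(a, b)), "regrid")
})

test_that("shape-correction fitting is self-consistent at phi = 1", {
  comps <- random_components(3, seed = 41)
  for (cc in seq_along(comps)) comps[[cc]]$shape_factor <- 1
  f <- formulation("B", c("C1", "C2", "C3"), c(0.4, 0.35, 0.25))
  target <- mix_size_distribution(f, comps)
  fit <- fit_shape_correction(target, f, comps, free_components = "C1")
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted_factors["C1"]), 1, tolerance = 1e-4)
  expect_lt(fit$rmse, 1e-8)
})

test_that("shape-correction fitting recovers a known factor", {
  comps <- random_components(3, seed = 43)
  for (cc in seq_along(comps)) comps[[cc]]$shape_factor <- 1
  f <- formulation("B", c("C1", "C2", "C3"), c(0.4, 0.35, 0.25))
  truth <- comps
  truth[[1]]$shape_factor <- 1.4
  target <- mix_size_distribution(f, truth)

  fit <- fit_shape_correction(target, f, comps, free_components = "C1")
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted_factors["C1"]), 1.4, tolerance = 1e-3)

  # with small frequency noise the factor is still recovered closely
  set.seed(99)
  noisy <- pmax(target$frequencies + rnorm(n_classes(target), 0, 1e-4), 0)
  noisy_dist <- freq_dist(target$grid, noisy / sum(noisy))
  fit2 <- fit_shape_correction(noisy_dist, f, comps, free_components = "C1")
  expect_equal(unname(fit2$fitted_factors["C1"]), 1.4, tolerance = 0.05)
})
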