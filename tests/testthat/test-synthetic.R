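small_cfg <- function(seed = 1, ...) {
  generator_config(seed = seed, n_blends = 12,
                   grid = default_size_grid(101),
                   ar_grid = default_ar_grid(51), ...)
}

test_that("components are reproducible, normalized and physically consistent", {
  cfg <- generator_config(seed = 7)
  c1 <- generate_component(cfg, 3)
  c2 <- generate_component(cfg, 3)
  expect_identical(c1, c2)
  expect_equal(n_classes(c1$psd), 1001L)
  expect_equal(n_classes(c1$ard), 1001L)
  expect_equal(sum(c1$psd$frequencies), 1, tolerance = 1e-12)
  expect_equal(sum(c1$ard$frequencies), 1, tolerance = 1e-12)
  for (i in 1:8) {
    cc <- generate_component(cfg, i)
    expect_lt(cc$bulk_density, cc$true_density)
    expect_gte(cc$true_density, cfg$true_density_range[1])
    expect_lte(cc$true_density, cfg$true_density_range[2])
    expect_gte(cc$bulk_density, cfg$bulk_density_range[1])
    expect_lte(cc$bulk_density, cfg$bulk_density_range[2])
  }
  # distinct indices give distinct materials
  expect_false(identical(generate_component(cfg, 1)$psd$frequencies,
                         generate_component(cfg, 2)$psd$frequencies))
})

test_that("blend datasets are reproducible and structurally complete", {
  ds1 <- generate_blend_dataset(small_cfg(seed = 5))
  ds2 <- generate_blend_dataset(small_cfg(seed = 5))
  expect_identical(ds1$flow, ds2$flow)
  expect_identical(ds1$mixtures[[3]]$psd$frequencies,
                   ds2$mixtures[[3]]$psd$frequencies)

  expect_length(ds1$formulations, 12)
  # every blend has exactly one flow record per pressure
  tab <- table(ds1$flow$blend_code)
  expect_true(all(tab == length(ds1$manifest$pressures)))
  expect_true(all(ds1$flow$ffc > 0))
  expect_gte(min(ds1$flow$pressure_kpa), 0.79)
  expect_lte(max(ds1$flow$pressure_kpa), 13.26)
  # more than one API label so grouped CV is possible
  expect_gt(length(unique(ds1$flow$api_label)), 1)
})

test_that("ground-truth mixtures equal the package's own forward models bit-exactly", {
  ds <- generate_blend_dataset(small_cfg(seed = 9))
  for (i in c(1, 5, 12)) {
    f <- ds$formulations[[i]]
    m <- ds$mixtures[[i]]
    expect_identical(m$psd$frequencies,
                     mix_size_distribution(f, ds$components)$frequencies)
    expect_identical(m$ard$frequencies,
                     mix_shape_distribution(f, ds$components)$frequencies)
    expect_identical(m$true_density,
                     mix_true_density(f, ds$components, "harmonic"))
    expect_identical(m$bulk_density,
                     mix_bulk_density(f, ds$components, "mass_weighted"))
    expect_gt(m$tapped_density, 0)
  }
})

test_that("generated FFC values span all three flow classes at default scale", {
  ds <- generate_blend_dataset(generator_config(seed = 1,
                                                grid = default_size_grid(101),
                                                ar_grid = default_ar_grid(51)))
  classes <- table(classify_flow(ds$flow$ffc))
  expect_true(all(classes > 0))
})

test_that("a noise-free dataset is recovered almost exactly by the pipeline", {
  # 100 blends: the PC scores encode the size percentile only
  # approximately, so recovery is limited by sample size, not noise
  cfg <- generator_config(seed = 31, n_blends = 100,
                          grid = default_size_grid(101),
                          ar_grid = default_ar_grid(51),
                          snr = Inf, tapped_noise_sd = 0)
  ds <- generate_blend_dataset(cfg)
  expect_equal(ds$manifest$ffc_noise_sd, 0)
  expect_equal(ds$flow$ffc, pmax(ds$flow$ffc_true, 0.3))

  psd_pca <- fit_distribution_pca(lapply(ds$mixtures, `[[`, "psd"))
  fm <- assemble_feature_matrix(ds$mixtures, "ffc", psd_pca,
                                pressures = cfg$pressures)
  sp <- split_by_formulation(ds$flow$blend_code, 0.25, seed = 32)
  # no noise, so a deep booster run to convergence cannot overfit
  m <- train_property_model(fm$features[sp$train, ],
                            scale_response(ds$flow$ffc[sp$train]),
                            "ffc", "extreme_gradient_boosting",
                            hyperparameters = list(nrounds = 1000L,
                                                   max_depth = 6L),
                            seed = 33)
  ev <- evaluate_model(m, fm$features[sp$test, ], ds$flow$ffc[sp$test])
  expect_gte(ev$r_squared, 0.99)
})
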