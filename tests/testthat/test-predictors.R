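test_that("response scaling maps the cohesive threshold to 0.5 and round trips", {
  expect_equal(scale_response(0), 0)
  expect_identical(scale_response(4, beta = 4), 0.5)
  expect_equal(scale_response(8, beta = 4), 0.75)
  y <- seq(0, 50, by = 0.25)
  expect_equal(unscale_response(scale_response(y)), y, tolerance = 1e-12)
  # strictly increasing into [0, 1)
  u <- scale_response(y)
  expect_true(all(diff(u) > 0) && all(u >= 0 & u < 1))
  # u < 0.5 exactly characterises the cohesive class
  expect_equal(u < 0.5, y < 4)
  expect_error(scale_response(-1), "non-negative")
  expect_error(unscale_response(1), "\\[0, 1\\)")
})

test_that("flow classification uses left-closed boundaries", {
  expect_equal(as.character(classify_flow(c(3.9, 4, 9.99, 10, 35))),
               c("cohesive", "easy_flowing", "easy_flowing",
                 "free_flowing", "free_flowing"))
  expect_error(classify_flow(0), "positive")
})

test_that("formulation-grouped splits never leak a blend and are reproducible", {
  codes <- rep(sprintf("B%02d", 1:47), each = 5)
  sp <- split_by_formulation(codes, test_fraction = 12 / 47, seed = 4)
  expect_length(sp$test_blends, 12)
  expect_length(sp$test, 60)
  expect_length(sp$train, 175)
  expect_length(intersect(unique(codes[sp$train]), unique(codes[sp$test])), 0)
  # all pressure replicates of a held-out blend travel together
  for (b in sp$test_blends) expect_equal(sum(codes[sp$test] == b), 5)
  sp2 <- split_by_formulation(codes, test_fraction = 12 / 47, seed = 4)
  expect_identical(sp, sp2)
  expect_error(split_by_formulation(rep("B1", 5), 0.5), "at least 2")
})

test_that("every family interpolates a noise-free linear response and is deterministic", {
  set.seed(8)
  X <- cbind(x1 = runif(120), x2 = runif(120), x3 = runif(120))
  y <- 0.2 + 0.5 * X[, 1] + 0.3 * X[, 2] - 0.2 * X[, 3]
  for (fam in c("random_forest", "gradient_boosting",
                "extreme_gradient_boosting", "support_vector")) {
    m <- train_property_model(X, y, "tapped", fam, seed = 5)
    pred <- predict_property(m, X)
    expect_gte(r2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2), 0.95)
    m2 <- train_property_model(X, y, "tapped", fam, seed = 5)
    expect_identical(predict_property(m2, X), pred)
    # batch prediction equals row-wise prediction
    rowwise <- vapply(1:5, function(i) {
      predict_property(m, X[i, , drop = FALSE])
    }, 0)
    expect_equal(rowwise, pred[1:5], tolerance = 1e-12)
  }
  expect_error(train_property_model(X, y, "tapped", "neural_net"), "arg")
  expect_error(train_property_model(X, c(y[-1], NA), "tapped", "random_forest"),
               "non-finite")
})

test_that("FFC models demand scaled responses and predict positive values", {
  set.seed(9)
  X <- cbind(a = runif(60), b = runif(60))
  ffc <- 2 + 20 * X[, 1]
  expect_error(train_property_model(X, ffc, "ffc", "random_forest"),
               "pre-scaled")
  m <- train_property_model(X, scale_response(ffc), "ffc", "random_forest",
                            seed = 2)
  pred <- predict_property(m, X)
  expect_true(all(is.finite(pred) & pred >= 0))
  expect_error(predict_property(m, cbind(a = 1)), "feature")
})

test_that("model evaluation matches closed-form metrics and counts every test row", {
  set.seed(10)
  X <- cbind(a = runif(80), b = runif(80))
  ffc <- pmax(1 + 18 * X[, 1] + rnorm(80, 0, 0.2), 0.5)
  m <- train_property_model(X, scale_response(ffc), "ffc", "random_forest",
                            seed = 3)
  ev <- evaluate_model(m, X, ffc)
  expect_equal(sum(ev$confusion), 80)
  expect_true(ev$rmse >= 0 && ev$rmse_scaled >= 0)

  # degenerate closed forms via a model evaluated against its own output
  pred <- predict_property(m, X)
  ev_perfect <- evaluate_model(m, X, pred)
  expect_equal(ev_perfect$r_squared, 1, tolerance = 1e-10)
  expect_equal(ev_perfect$rmse, 0, tolerance = 1e-8)
  expect_equal(sum(diag(ev_perfect$confusion)), 80)

  # constant prediction at the mean has R2 = 0 by definition
  truth <- c(1, 2, 3, 4)
  expect_equal(1 - sum((truth - mean(truth))^2) / sum((truth - mean(truth))^2), 0)
})

test_that("leave-API-out folds are label-pure and partition the dataset", {
  ds <- generate_blend_dataset(generator_config(seed = 11, n_blends = 25,
                                                grid = default_size_grid(101),
                                                ar_grid = default_ar_grid(51)))
  psd_pca <- fit_distribution_pca(lapply(ds$mixtures, `[[`, "psd"))
  fm <- assemble_feature_matrix(ds$mixtures, "ffc", psd_pca,
                                pressures = ds$manifest$pressures)
  stopifnot(identical(fm$blend_code, ds$flow$blend_code))
  cv <- leave_api_out_cv(fm$features, ds$flow$ffc, ds$flow$api_label,
                         family = "random_forest", seed = 12)
  labels <- unique(ds$flow$api_label)
  expect_setequal(names(cv$fold_rmse), labels)
  expect_equal(sum(cv$fold_n), nrow(fm$features))
  expect_true(all(cv$fold_rmse >= 0))
  expect_equal(cv$mean_rmse, mean(cv$fold_rmse))
  expect_error(leave_api_out_cv(fm$features, ds$flow$ffc,
                                rep("one", nrow(fm$features))),
               "at least 2")
})
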