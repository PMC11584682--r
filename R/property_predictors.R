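# Data-driven tapped-density and FFC regressors ----------------------------
#
# FFC responses are scaled before training with u = 1 - 2^(-y/beta),
# beta = 4, so the cohesive class (FFC < 4) occupies exactly the lower half
# of the unit interval and both flow regimes carry comparable weight in the
# loss. Tapped density trains untransformed. Four regressor families are
# supported; train/test splitting is always grouped by blend so that no
# formulation leaks across the split.

#' Flow-classification-aware response scaling
#'
#' Maps an FFC value `y >= 0` to `u = 1 - 2^(-y/beta)` in `[0, 1)`. With
#' the default threshold `beta = 4` the cohesive boundary FFC = 4 maps to
#' exactly `u = 0.5`, so cohesive powders occupy the lower half of the
#' scaled domain and free/easy-flowing the upper half.
#'
#' @param y FFC value(s), non-negative.
#' @param beta Positive threshold parameter.
#' @return Scaled response(s) in `[0, 1)`.
#' @export
scale_response <- function(y, beta = 4) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (any(y < 0)) stop("response y must be non-negative", call. = FALSE)
  1 - 2^(-y / beta)
}

#' Invert the response scaling
#'
#' `y = -beta * log2(1 - u)`. `u` is clipped to at most `1 - 1e-9` before
#' inversion so the result stays finite.
#'
#' @param u Scaled response(s) in `[0, 1)`.
#' @param beta Positive threshold parameter.
#' @return FFC value(s) on the original scale.
#' @export
unscale_response <- function(u, beta = 4) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (any(u >= 1) || any(u < 0)) {
    stop("scaled response u must lie in [0, 1)", call. = FALSE)
  }
  u <- pmin(u, 1 - 1e-9)
  -beta * log2(1 - u) + 0  # + 0 normalizes IEEE negative zero at u = 0
}

#' Classify powder flow behaviour from FFC
#'
#' Standard shear-cell flow classes with left-closed boundaries:
#' cohesive (FFC < 4), easy-flowing (4 <= FFC < 10), free-flowing
#' (FFC >= 10).
#'
#' @param ffc Positive FFC value(s).
#' @return Factor with levels `cohesive`, `easy_flowing`, `free_flowing`.
#' @export
classify_flow <- function(ffc) {
  if (any(ffc <= 0)) stop("ffc must be positive", call. = FALSE)
  cut(ffc, breaks = c(0, 4, 10, Inf), right = FALSE,
      labels = c("cohesive", "easy_flowing", "free_flowing"))
}

#' Formulation-grouped train/test split
#'
#' Holds out whole blends: every row of a held-out blend (e.g. all its
#' pressure replicates) goes to the test side together.
#'
#' @param blend_codes Character vector, one entry per dataset row.
#' @param test_fraction Fraction of distinct blends held out.
#' @param seed Integer seed making the split reproducible.
#' @return List with integer row indices `train` and `test`, plus
#'   `test_blends`.
#' @export
split_by_formulation <- function(blend_codes, test_fraction = 0.25, seed = 1L) {
  blends <- unique(blend_codes)
  if (length(blends) < 2L) {
    stop("need at least 2 distinct blends to split", call. = FALSE)
  }
  n_test <- max(1L, round(test_fraction * length(blends)))
  if (n_test >= length(blends)) n_test <- length(blends) - 1L
  set.seed(seed)
  test_blends <- sample(blends, n_test)
  test <- which(blend_codes %in% test_blends)
  list(train = setdiff(seq_along(blend_codes), test), test = test,
       test_blends = test_blends)
}

model_families <- c("random_forest", "gradient_boosting",
                    "extreme_gradient_boosting", "support_vector")

default_hyperparameters <- function(family) {
  switch(family,
    random_forest = list(ntree = 500L),
    # classic gradient boosting: shallow trees, slow learning, no
    # regularization penalty, full-sample deterministic boosting
    gradient_boosting = list(nrounds = 500L, eta = 0.05, max_depth = 3L,
                             lambda = 0, alpha = 0, subsample = 1,
                             colsample_bytree = 1),
    extreme_gradient_boosting = list(nrounds = 500L, eta = 0.05, max_depth = 4L,
                                     lambda = 1, alpha = 0, subsample = 0.8,
                                     colsample_bytree = 0.8),
    support_vector = list(kernel = "radial", cost = 1, gamma = NULL,
                          epsilon = 0.1))
}

#' Train a tapped-density or FFC regressor
#'
#' Fits one of four regressor families on an assembled feature matrix.
#' FFC responses are expected already on the scaled `u` domain (see
#' [scale_response()]); the trained model records the transform so
#' [predict_property()] can return original-scale FFC values. Training is
#' deterministic given `seed`.
#'
#' @param features Numeric feature matrix (rows = data points).
#' @param responses Numeric response vector; for `target = "ffc"` these are
#'   scaled values in `[0, 1)`.
#' @param target `"tapped"` or `"ffc"`.
#' @param family One of `"random_forest"`, `"gradient_boosting"`,
#'   `"extreme_gradient_boosting"`, `"support_vector"`.
#' @param hyperparameters Named list overriding the family defaults.
#' @param seed Integer seed.
#' @param beta Response-scaling threshold recorded for FFC models.
#' @return Object of class `property_model` with the fitted estimator and a
#'   training manifest (family, target, seed, feature layout, transform).
#' @export
train_property_model <- function(features, responses,
                                 target = c("tapped", "ffc"),
                                 family = model_families,
                                 hyperparameters = list(), seed = 1L,
                                 beta = 4) {
  target <- match.arg(target)
  family <- match.arg(family)
  features <- as.matrix(features)
  responses <- as.numeric(responses)
  if (nrow(features) != length(responses)) {
    stop("features and responses are not aligned", call. = FALSE)
  }
  if (any(!is.finite(features)) || any(!is.finite(responses))) {
    stop("non-finite values in features or responses", call. = FALSE)
  }
  if (target == "ffc" && (any(responses < 0) || any(responses >= 1))) {
    stop("ffc responses must be pre-scaled to [0, 1) with scale_response()",
         call. = FALSE)
  }
  hp <- utils::modifyList(default_hyperparameters(family), hyperparameters)
  set.seed(seed)
  fit <- switch(family,
    random_forest = randomForest::randomForest(
      x = features, y = responses, ntree = hp$ntree, keep.inbag = TRUE),
    gradient_boosting = ,
    extreme_gradient_boosting = xgboost::xgboost(
      x = features, y = responses, nrounds = hp$nrounds,
      learning_rate = hp$eta, max_depth = hp$max_depth,
      reg_lambda = hp$lambda, reg_alpha = hp$alpha,
      subsample = hp$subsample, colsample_bytree = hp$colsample_bytree,
      objective = "reg:squarederror", nthreads = 1L, seed = seed,
      verbosity = 0),
    support_vector = {
      if (is.null(hp$gamma)) hp$gamma <- 1 / ncol(features)
      e1071::svm(x = features, y = responses, type = "eps-regression",
                 kernel = hp$kernel, cost = hp$cost, gamma = hp$gamma,
                 epsilon = hp$epsilon, scale = TRUE)
    })
  structure(list(fit = fit, target = target, family = family,
                 feature_names = colnames(features),
                 transform = if (target == "ffc") list(beta = beta) else NULL,
                 manifest = list(seed = seed, n_train = nrow(features),
                                 hyperparameters = hp)),
            class = "property_model")
}

#' @export
print.property_model <- function(x, ...) {
  cat(sprintf("<property_model> target: %s, family: %s\n", x$target, x$family))
  cat(sprintf("  trained on %d points, %d features (%s)\n",
              x$manifest$n_train, length(x$feature_names),
              paste(x$feature_names, collapse = ", ")))
  if (!is.null(x$transform)) {
    cat(sprintf("  response scaled with u = 1 - 2^(-y/%g); predictions returned on the FFC scale\n",
                x$transform$beta))
  }
  invisible(x)
}

check_feature_layout <- function(model, features) {
  features <- as.matrix(features)
  if (!is.null(model$feature_names) && !is.null(colnames(features))) {
    if (!identical(colnames(features), model$feature_names)) {
      stop("feature layout does not match the trained model", call. = FALSE)
    }
  } else if (ncol(features) != length(model$feature_names)) {
    stop("feature count does not match the trained model", call. = FALSE)
  }
  features
}

# raw predictions on the model's training scale (u-domain for FFC)
predict_scaled <- function(model, features) {
  features <- check_feature_layout(model, features)
  switch(model$family,
    random_forest = as.numeric(predict(model$fit, features)),
    gradient_boosting = ,
    extreme_gradient_boosting = as.numeric(predict(model$fit, features)),
    support_vector = as.numeric(predict(model$fit, features)))
}

#' Predict with a trained property model
#'
#' FFC models predict on the scaled domain internally; the output is
#' clipped to `[0, 1 - 1e-9]` and inverted with [unscale_response()] so the
#' returned values are on the original FFC scale.
#'
#' @param model A [train_property_model()] fit.
#' @param features Feature matrix matching the model's layout.
#' @return Numeric predictions on the original response scale.
#' @export
predict_property <- function(model, features) {
  stopifnot(inherits(model, "property_model"))
  pred <- predict_scaled(model, features)
  if (model$target == "ffc") {
    pred <- unscale_response(pmin(pmax(pred, 0), 1 - 1e-9),
                             beta = model$transform$beta)
  }
  pred
}

#' @export
predict.property_model <- function(object, newdata, ...) {
  predict_property(object, newdata)
}

r_squared <- function(truth, pred) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NaN)
  1 - sum((truth - pred)^2) / ss_tot
}

#' Evaluate a trained property model on a test set
#'
#' Reports R-squared and RMSE on the original response scale; FFC models
#' additionally get scaled-domain (`u`) metrics and a 3x3 flow-class
#' confusion matrix (rows = truth, columns = prediction).
#'
#' @param model A [train_property_model()] fit.
#' @param features Test feature matrix.
#' @param truth Test responses on the original scale.
#' @return Object of class `metrics_report`: `r_squared`, `rmse`, and for
#'   FFC `r_squared_scaled`, `rmse_scaled`, `confusion`.
#' @export
evaluate_model <- function(model, features, truth) {
  stopifnot(inherits(model, "property_model"))
  truth <- as.numeric(truth)
  if (length(truth) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict_property(model, features)
  out <- list(target = model$target, family = model$family, n = length(truth),
              r_squared = r_squared(truth, pred),
              rmse = sqrt(mean((truth - pred)^2)))
  if (model$target == "ffc") {
    beta <- model$transform$beta
    u_true <- scale_response(truth, beta)
    u_pred <- predict_scaled(model, features)
    out$r_squared_scaled <- r_squared(u_true, u_pred)
    out$rmse_scaled <- sqrt(mean((u_true - u_pred)^2))
    out$confusion <- table(truth = classify_flow(truth),
                           predicted = classify_flow(pmax(pred, 1e-9)))
    out$class_accuracy <- sum(diag(out$confusion)) / length(truth)
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s / %s, n = %d\n", x$target, x$family, x$n))
  cat(sprintf("  R2 = %.3f, RMSE = %.4g (original scale)\n", x$r_squared, x$rmse))
  if (!is.null(x$rmse_scaled)) {
    cat(sprintf("  R2 = %.3f, RMSE = %.4g (scaled u domain)\n",
                x$r_squared_scaled, x$rmse_scaled))
    cat(sprintf("  flow-class accuracy = %.3f\n", x$class_accuracy))
    print(x$confusion)
  }
  if (!is.null(x$fold_rmse)) {
    cat("  per-fold RMSE (scaled domain):\n")
    for (nm in names(x$fold_rmse)) {
      cat(sprintf("    %-10s %.4g\n", nm, x$fold_rmse[[nm]]))
    }
    cat(sprintf("  mean fold RMSE = %.4g\n", x$mean_rmse))
  }
  invisible(x)
}

#' Leave-API-out cross-validation of an FFC model
#'
#' One fold per distinct API label: the model is retrained without any
#' blend containing the held-out API and evaluated on those blends, probing
#' generalisation to chemically new actives. RMSEs are reported on the
#' scaled `u` domain (and on the FFC scale for reference).
#'
#' @param features Feature matrix.
#' @param ffc FFC responses on the original scale.
#' @param api_labels Character vector of API identities per row
#'   (`"placebo"` allowed as its own fold).
#' @param family Regressor family.
#' @param hyperparameters Overrides for the family defaults.
#' @param seed Integer seed.
#' @param beta Response-scaling threshold.
#' @return A `metrics_report` with `fold_rmse` (named, scaled domain),
#'   `fold_rmse_ffc`, `mean_rmse` and fold sizes.
#' @export
leave_api_out_cv <- function(features, ffc, api_labels,
                             family = model_families,
                             hyperparameters = list(), seed = 1L, beta = 4) {
  family <- match.arg(family)
  features <- as.matrix(features)
  labels <- unique(api_labels)
  if (length(labels) < 2L) {
    stop("need at least 2 distinct API labels for leave-API-out CV", call. = FALSE)
  }
  u <- scale_response(ffc, beta)
  fold_rmse <- fold_rmse_ffc <- stats::setNames(numeric(0), character(0))
  fold_n <- integer(0)
  for (lab in labels) {
    test <- which(api_labels == lab)
    if (length(test) == 0L) {
      warning(sprintf("API label '%s' has no rows; fold skipped", lab))
      next
    }
    model <- train_property_model(features[-test, , drop = FALSE], u[-test],
                                  target = "ffc", family = family,
                                  hyperparameters = hyperparameters,
                                  seed = seed, beta = beta)
    u_pred <- predict_scaled(model, features[test, , drop = FALSE])
    y_pred <- predict_property(model, features[test, , drop = FALSE])
    fold_rmse[lab] <- sqrt(mean((u[test] - u_pred)^2))
    fold_rmse_ffc[lab] <- sqrt(mean((ffc[test] - y_pred)^2))
    fold_n[lab] <- length(test)
  }
  structure(list(target = "ffc", family = family, n = length(ffc),
                 r_squared = NA_real_, rmse = NA_real_,
                 fold_rmse = fold_rmse, fold_rmse_ffc = fold_rmse_ffc,
                 fold_n = fold_n, mean_rmse = mean(fold_rmse)),
            class = "metrics_report")
}
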