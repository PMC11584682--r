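# Model-based uncertainty quantification -----------------------------------
#
# Two interval constructions for ensemble regressors:
#  * ensemble interval — point = mean of the per-tree predictions, standard
#    error = sqrt(variance of tree predictions + forest MSE), normal
#    critical value;
#  * leverage interval — classic regression prediction interval
#    t * S * sqrt(1 + 1/n + leverage), where the leverage is the
#    Mahalanobis-type quadratic form of the query point about the training
#    feature mean.
# The relative standard deviation (RSD) divides the full interval width by
# the point prediction.

#' Two-sided normal critical value
#' @param alpha Significance level in (0, 1).
#' @return `qnorm(1 - alpha/2)`.
#' @export
normal_critical_value <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  stats::qnorm(1 - alpha / 2)
}

#' Two-sided Student-t critical value
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return `qt(1 - alpha/2, df)`.
#' @export
t_critical_value <- function(alpha = 0.05, df) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  stats::qt(1 - alpha / 2, df)
}

new_prediction_interval <- function(point, half_width, se = NA_real_) {
  structure(list(point = point, lower = point - half_width,
                 upper = point + half_width, se = se,
                 rsd = if (point > 0) 2 * half_width / point else NA_real_),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cat(sprintf("<prediction_interval> %.4g  [%.4g, %.4g]", x$point, x$lower, x$upper))
  if (!is.na(x$rsd)) cat(sprintf("  RSD = %.3g", x$rsd))
  cat("\n")
  invisible(x)
}

# population variance (divide by n), the convention used for the spread of
# the per-tree predictions
pop_var <- function(x) mean((x - mean(x))^2)

#' Ensemble-variance prediction interval
#'
#' For a random-forest-type ensemble: the point prediction is the mean of
#' the per-tree predictions; the standard error is the square root of the
#' sum of the (population) variance of the tree predictions and the
#' forest's residual variance, estimated by its mean squared error.
#'
#' @param tree_predictions Per-tree predictions for one query point
#'   (length >= 2).
#' @param mse Forest mean squared error (residual variance estimate).
#' @param alpha Significance level.
#' @return A `prediction_interval` with `point`, `lower`, `upper`, `se`,
#'   `rsd`.
#' @export
ensemble_interval <- function(tree_predictions, mse, alpha = 0.05) {
  tree_predictions <- as.numeric(tree_predictions)
  if (length(tree_predictions) < 2L) {
    stop("need at least 2 tree predictions", call. = FALSE)
  }
  if (mse < 0) stop("mse must be non-negative", call. = FALSE)
  point <- mean(tree_predictions)
  se <- sqrt(pop_var(tree_predictions) + mse)
  new_prediction_interval(point, normal_critical_value(alpha) * se, se = se)
}

#' Leverage-corrected prediction interval
#'
#' Half-width `t(alpha/2, n-1) * S * sqrt(1 + 1/n + h(x))` where
#' `h(x) = (x - xbar) Sxx^{-1} (x - xbar)'` is the leverage of the query
#' point with respect to the training features (unbiased covariance;
#' Moore-Penrose pseudo-inverse with a warning when the covariance is
#' singular).
#'
#' @param x Query feature vector.
#' @param train_features Training feature matrix (rows = points).
#' @param point Point prediction for `x` (e.g. the ensemble mean).
#' @param s Residual standard deviation of the model on its training data.
#' @param alpha Significance level.
#' @param n Test-sample count setting the t degrees of freedom `n - 1`;
#'   defaults to the number of training rows.
#' @return A `prediction_interval`; also carries `leverage`.
#' @export
leverage_interval <- function(x, train_features, point, s, alpha = 0.05,
                              n = nrow(train_features)) {
  train_features <- as.matrix(train_features)
  x <- as.numeric(x)
  if (length(x) != ncol(train_features)) {
    stop("query point dimension does not match training features", call. = FALSE)
  }
  if (s < 0) stop("residual sd must be non-negative", call. = FALSE)
  xbar <- colMeans(train_features)
  sxx <- stats::cov(train_features)
  inv <- tryCatch(solve(sxx), error = function(e) NULL)
  if (is.null(inv)) {
    warning("training feature covariance is singular; using pseudo-inverse")
    inv <- MASS::ginv(sxx)
  }
  d <- x - xbar
  lev <- max(0, as.numeric(t(d) %*% inv %*% d))
  half <- t_critical_value(alpha, n - 1) * s * sqrt(1 + 1 / n + lev)
  out <- new_prediction_interval(point, half, se = s)
  out$leverage <- lev
  out
}

#' Relative standard deviation of a prediction
#'
#' Full interval width divided by the point prediction. High RSD flags
#' predictions in data-sparse regions of feature space (typically the
#' free-flowing, high-FFC powders).
#'
#' @param interval A `prediction_interval`, or the lower bound if `upper`
#'   and `point` are given separately.
#' @param upper,point Optional scalars when not passing an interval object.
#' @return RSD (>= 0).
#' @export
relative_standard_deviation <- function(interval, upper = NULL, point = NULL) {
  if (inherits(interval, "prediction_interval")) {
    lower <- interval$lower; upper <- interval$upper; point <- interval$point
  } else {
    lower <- interval
  }
  if (is.null(upper) || is.null(point)) {
    stop("provide a prediction_interval or (lower, upper, point)", call. = FALSE)
  }
  if (point <= 0) stop("point prediction must be positive", call. = FALSE)
  (upper - lower) / point
}

#' Random-forest prediction intervals for a batch of query points
#'
#' Convenience wrapper applying [ensemble_interval()] per query point of a
#' fitted random-forest property model, using the per-tree predictions and
#' the forest's out-of-bag MSE. FFC intervals are mapped back to the
#' original scale by inverting the response transform at the point and both
#' bounds (monotone transform, so coverage is preserved).
#'
#' @param model A random-forest [train_property_model()] fit.
#' @param features Query feature matrix.
#' @param alpha Significance level.
#' @return Data frame with columns `point`, `lower`, `upper`, `rsd` on the
#'   original response scale.
#' @export
forest_prediction_intervals <- function(model, features, alpha = 0.05) {
  stopifnot(inherits(model, "property_model"))
  if (model$family != "random_forest") {
    stop("ensemble intervals require a random_forest model", call. = FALSE)
  }
  features <- check_feature_layout(model, features)
  all_trees <- predict(model$fit, features, predict.all = TRUE)$individual
  mse <- utils::tail(model$fit$mse, 1)
  rows <- lapply(seq_len(nrow(features)), function(i) {
    iv <- ensemble_interval(all_trees[i, ], mse, alpha)
    if (model$target == "ffc") {
      beta <- model$transform$beta
      clip <- function(u) pmin(pmax(u, 0), 1 - 1e-9)
      pt <- unscale_response(clip(iv$point), beta)
      lo <- unscale_response(clip(iv$lower), beta)
      hi <- unscale_response(clip(iv$upper), beta)
      data.frame(point = pt, lower = lo, upper = hi,
                 rsd = if (pt > 0) (hi - lo) / pt else NA_real_)
    } else {
      data.frame(point = iv$point, lower = iv$lower, upper = iv$upper,
                 rsd = iv$rsd)
    }
  })
  do.call(rbind, rows)
}
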