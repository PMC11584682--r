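# PCA feature compression of predicted distributions -----------------------
#
# The 1001-class predicted distributions are too wide to feed a regressor
# directly; PCA on the predicted mixture distributions compresses each to
# a few principal scores. Column-mean centering only, no variance scaling
# (all classes already live on one normalized frequency scale). Loading
# signs are fixed so the largest-magnitude element of each loading is
# positive, making score files reproducible across platforms.

#' Fit a PCA model to a set of frequency distributions
#'
#' @param distributions List of [freq_dist()] objects on one shared grid
#'   (at least `n_components + 1` of them).
#' @param n_components Number of principal components to retain.
#' @return Object of class `distribution_pca`: `mean`, `loadings`
#'   (n_components x n_classes, orthonormal rows), `explained_variance_ratio`
#'   and the training `grid`.
#' @export
fit_distribution_pca <- function(distributions, n_components = 3L) {
  stopifnot(length(distributions) >= 1L)
  grid <- check_shared_grid(distributions)
  if (length(distributions) < n_components + 1L) {
    stop(sprintf("need at least %d distributions to fit %d components",
                 n_components + 1L, n_components), call. = FALSE)
  }
  X <- do.call(rbind, lapply(distributions, `[[`, "frequencies"))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  load <- t(pc$rotation[, seq_len(k), drop = FALSE])
  # sign convention: largest-|.| element of each loading is positive
  for (i in seq_len(k)) {
    if (load[i, which.max(abs(load[i, ]))] < 0) load[i, ] <- -load[i, ]
  }
  var_all <- pc$sdev^2
  structure(list(mean = pc$center,
                 loadings = load,
                 explained_variance_ratio = var_all[seq_len(k)] / sum(var_all),
                 n_components = k,
                 grid = grid),
            class = "distribution_pca")
}

#' @export
print.distribution_pca <- function(x, ...) {
  cat(sprintf("<distribution_pca> %d components over %d %s classes\n",
              x$n_components, length(x$mean), x$grid$kind))
  cat(sprintf("  explained variance ratio: %s (cum. %.3f)\n",
              paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", "),
              sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project distributions onto fitted principal components
#'
#' @param pca A [fit_distribution_pca()] model.
#' @param distributions A single [freq_dist()] or a list of them, on the
#'   grid the model was fitted on.
#' @return Numeric matrix of scores, one row per distribution, columns
#'   `PC1..PCk`.
#' @export
project_distribution <- function(pca, distributions) {
  stopifnot(inherits(pca, "distribution_pca"))
  if (inherits(distributions, "freq_dist")) distributions <- list(distributions)
  for (d in distributions) {
    if (!same_grid(d$grid, pca$grid)) {
      stop("distribution grid does not match the PCA training grid", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(distributions, `[[`, "frequencies"))
  scores <- sweep(X, 2, pca$mean) %*% t(pca$loadings)
  colnames(scores) <- paste0("PC", seq_len(pca$n_components))
  scores
}

#' Assemble the regression feature vector for one blend
#'
#' Fixed feature layouts per target property:
#' \describe{
#'   \item{tapped}{PSD PC1-3, ARD PC1-3, blend true density, blend bulk
#'     density (8 features).}
#'   \item{ffc}{PSD PC1-3, blend true density, blend bulk density,
#'     consolidation pressure (6 features); shape scores are excluded,
#'     having shown only marginal influence on flowability.}
#' }
#'
#' @param mixture A [mixture_properties()] object (predicted distributions
#'   and densities).
#' @param target `"tapped"` or `"ffc"`.
#' @param psd_pca PCA model fitted on predicted blend PSDs.
#' @param ard_pca PCA model fitted on predicted blend ARDs (tapped target
#'   only).
#' @param pressure Consolidation pressure in kPa (ffc target only).
#' @return Named numeric feature vector.
#' @export
assemble_feature_vector <- function(mixture, target = c("tapped", "ffc"),
                                    psd_pca, ard_pca = NULL, pressure = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(mixture, "mixture_properties"))
  psd_scores <- drop(project_distribution(psd_pca, mixture$psd))
  if (target == "tapped") {
    if (is.null(ard_pca)) stop("tapped target requires an ARD PCA model", call. = FALSE)
    ard_scores <- drop(project_distribution(ard_pca, mixture$ard))
    out <- c(psd_scores, ard_scores, mixture$true_density, mixture$bulk_density)
    names(out) <- c(paste0("psd_pc", seq_along(psd_scores)),
                    paste0("ard_pc", seq_along(ard_scores)),
                    "true_density", "bulk_density")
  } else {
    if (is.null(pressure)) {
      stop("ffc target requires a consolidation pressure", call. = FALSE)
    }
    out <- c(psd_scores, mixture$true_density, mixture$bulk_density, pressure)
    names(out) <- c(paste0("psd_pc", seq_along(psd_scores)),
                    "true_density", "bulk_density", "pressure_kpa")
  }
  if (any(!is.finite(out))) stop("non-finite feature value", call. = FALSE)
  out
}

#' Assemble the feature matrix for a set of blends
#'
#' Row-wise application of [assemble_feature_vector()]. For the FFC target
#' each blend contributes one row per consolidation pressure.
#'
#' @param mixtures List of [mixture_properties()] objects.
#' @param target `"tapped"` or `"ffc"`.
#' @param psd_pca,ard_pca PCA models as in [assemble_feature_vector()].
#' @param pressures Numeric vector of consolidation pressures applied to
#'   every blend (ffc target only).
#' @return List with `features` (numeric matrix) and `blend_code`
#'   (character vector aligned with the rows).
#' @export
assemble_feature_matrix <- function(mixtures, target = c("tapped", "ffc"),
                                    psd_pca, ard_pca = NULL, pressures = NULL) {
  target <- match.arg(target)
  rows <- list(); codes <- character(0)
  for (m in mixtures) {
    if (target == "tapped") {
      rows[[length(rows) + 1L]] <-
        assemble_feature_vector(m, "tapped", psd_pca, ard_pca)
      codes <- c(codes, m$blend_code)
    } else {
      for (p in pressures) {
        rows[[length(rows) + 1L]] <-
          assemble_feature_vector(m, "ffc", psd_pca, pressure = p)
        codes <- c(codes, m$blend_code)
      }
    }
  }
  list(features = do.call(rbind, rows), blend_code = codes)
}
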