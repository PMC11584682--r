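# Top-level hybrid blend-property model -------------------------------------
#
# One fitting function ties the stages together: analytic mixing of
# distributions and densities, PCA feature compression, and the
# data-driven tapped-density / FFC regressors. The fitted object predicts
# every blend property for a new formulation from raw-material data alone.

#' Fit the hybrid powder blend property model
#'
#' Runs the full pipeline on a training set of formulations: predicts each
#' training blend's PSD, ARD and densities from the component library with
#' the analytic mixture models, fits PCA models to the predicted
#' distributions, and trains the data-driven FFC regressor (and, when
#' tapped-density measurements are supplied, the tapped-density regressor)
#' on the assembled features.
#'
#' @param components Component library (list of [powder_component()]); all
#'   PSDs must share one size grid and all ARDs one aspect-ratio grid.
#' @param formulations Training formulations (list of [formulation()]).
#' @param flow Data frame of flow measurements with columns `blend_code`,
#'   `pressure_kpa`, `ffc` (as from [read_flow_table()]).
#' @param tapped Optional named numeric vector of measured tapped densities
#'   keyed by blend code.
#' @param family Regressor family for both data-driven models.
#' @param n_components Number of principal components retained per
#'   distribution.
#' @param beta FFC response-scaling threshold.
#' @param hyperparameters Overrides for the regressor defaults.
#' @param seed Integer seed controlling regressor training.
#' @return Object of class `powder_blend_model`.
#' @seealso [predict.powder_blend_model()]
#' @export
powder_blend_model <- function(components, formulations, flow, tapped = NULL,
                               family = "random_forest", n_components = 3L,
                               beta = 4, hyperparameters = list(), seed = 1L) {
  mixtures <- lapply(formulations, function(f) {
    predict_mixture_distributions(f, components)
  })
  codes <- vapply(mixtures, `[[`, "", "blend_code")
  psd_pca <- fit_distribution_pca(lapply(mixtures, `[[`, "psd"), n_components)
  ard_pca <- fit_distribution_pca(lapply(mixtures, `[[`, "ard"), n_components)

  # FFC model: one row per flow measurement
  idx <- match(flow$blend_code, codes)
  if (anyNA(idx)) {
    stop(sprintf("flow table references unknown blend(s): %s",
                 paste(unique(flow$blend_code[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  feat <- do.call(rbind, lapply(seq_len(nrow(flow)), function(i) {
    assemble_feature_vector(mixtures[[idx[i]]], "ffc", psd_pca,
                            pressure = flow$pressure_kpa[i])
  }))
  ffc_model <- train_property_model(feat, scale_response(flow$ffc, beta),
                                    target = "ffc", family = family,
                                    hyperparameters = hyperparameters,
                                    seed = seed, beta = beta)

  tapped_model <- NULL
  if (!is.null(tapped)) {
    tidx <- match(names(tapped), codes)
    if (anyNA(tidx)) {
      stop("tapped measurements reference unknown blend codes", call. = FALSE)
    }
    tfeat <- do.call(rbind, lapply(tidx, function(i) {
      assemble_feature_vector(mixtures[[i]], "tapped", psd_pca, ard_pca)
    }))
    tapped_model <- train_property_model(tfeat, as.numeric(tapped),
                                         target = "tapped", family = family,
                                         hyperparameters = hyperparameters,
                                         seed = seed)
  }

  structure(list(components = components, psd_pca = psd_pca,
                 ard_pca = ard_pca, ffc_model = ffc_model,
                 tapped_model = tapped_model, beta = beta,
                 train_codes = codes, family = family, seed = seed),
            class = "powder_blend_model")
}

#' Analytic mixture predictions for one formulation
#'
#' Applies the probabilistic PSD mixture model, the mass-over-true-density
#' ARD mixing rule, the harmonic true-density rule and the mass-weighted
#' bulk-density rule.
#'
#' @param form A [formulation()].
#' @param components Component library.
#' @return A [mixture_properties()] (tapped density and FFC unset).
#' @export
predict_mixture_distributions <- function(form, components) {
  mixture_properties(
    form$blend_code,
    psd = mix_size_distribution(form, components),
    ard = mix_shape_distribution(form, components),
    true_density = mix_true_density(form, components, "harmonic"),
    bulk_density = mix_bulk_density(form, components, "mass_weighted"))
}

#' Predict blend properties for new formulations
#'
#' @param object A fitted [powder_blend_model()].
#' @param formulations List of [formulation()] objects (components must be
#'   present in the model's library).
#' @param pressures Consolidation pressures (kPa) at which to predict FFC.
#' @param alpha Significance level for the FFC prediction intervals
#'   (random-forest family only).
#' @param ... Unused.
#' @return List of [mixture_properties()], one per formulation, with
#'   predicted distributions, densities, tapped density (when that model
#'   was trained) and per-pressure FFC predictions with intervals.
#' @export
predict.powder_blend_model <- function(object, formulations,
                                       pressures = seq(0.79, 13.26,
                                                       length.out = 5),
                                       alpha = 0.05, ...) {
  if (inherits(formulations, "formulation")) formulations <- list(formulations)
  lapply(formulations, function(f) {
    m <- predict_mixture_distributions(f, object$components)
    tapped <- NA_real_
    if (!is.null(object$tapped_model)) {
      tv <- assemble_feature_vector(m, "tapped", object$psd_pca, object$ard_pca)
      tapped <- predict_property(object$tapped_model, matrix(tv, nrow = 1,
                                 dimnames = list(NULL, names(tv))))
    }
    feat <- do.call(rbind, lapply(pressures, function(p) {
      assemble_feature_vector(m, "ffc", object$psd_pca, pressure = p)
    }))
    ffc <- data.frame(pressure_kpa = pressures,
                      ffc = predict_property(object$ffc_model, feat))
    if (object$ffc_model$family == "random_forest") {
      iv <- forest_prediction_intervals(object$ffc_model, feat, alpha)
      ffc$lower <- iv$lower; ffc$upper <- iv$upper; ffc$rsd <- iv$rsd
    }
    mixture_properties(f$blend_code, psd = m$psd, ard = m$ard,
                       true_density = m$true_density,
                       bulk_density = m$bulk_density,
                       tapped_density = tapped, ffc_by_pressure = ffc)
  })
}

#' @export
print.powder_blend_model <- function(x, ...) {
  cat("<powder_blend_model> hybrid blend-property model\n")
  cat(sprintf("  component library: %d materials; trained on %d blends\n",
              length(x$components), length(x$train_codes)))
  cat(sprintf("  PSD PCA: %d scores (%.0f%% variance); ARD PCA: %d scores (%.0f%% variance)\n",
              x$psd_pca$n_components,
              100 * sum(x$psd_pca$explained_variance_ratio),
              x$ard_pca$n_components,
              100 * sum(x$ard_pca$explained_variance_ratio)))
  cat(sprintf("  FFC regressor: %s (response scaled, beta = %g)\n",
              x$ffc_model$family, x$beta))
  cat(sprintf("  tapped-density regressor: %s\n",
              if (is.null(x$tapped_model)) "not trained" else x$tapped_model$family))
  invisible(x)
}

#' @export
summary.powder_blend_model <- function(object, ...) {
  print(object)
  cat("\nFFC model manifest:\n")
  cat(sprintf("  seed %d, %d training rows, features: %s\n",
              object$ffc_model$manifest$seed, object$ffc_model$manifest$n_train,
              paste(object$ffc_model$feature_names, collapse = ", ")))
  invisible(object)
}
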