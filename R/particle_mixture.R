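# Probabilistic mixture model for particle size and shape ------------------
#
# A blend's number-based PSD is a finite mixture of the component PSDs,
# n_mix,i = sum_j lambda_j n_j,i, where the membership weight lambda_j is
# the fraction of all particles in the blend that belong to component j.
# Under a spherical-particle volume model with a per-component shape
# correction factor phi_j,
#
#   lambda_j  propto  C_j / (rho_t,j phi_j) * sum_i 1/d_j,i^3
#
# with C_j the mass fraction, rho_t,j the true density and d_j,i the class
# diameters. The shape (aspect-ratio) distribution mixes with mass-over-
# true-density weights instead.

check_shared_grid <- function(dists, what = "distribution") {
  g <- dists[[1]]$grid
  for (d in dists[-1]) {
    if (!same_grid(d$grid, g)) {
      stop(sprintf("components' %ss are on different grids; regrid() them first",
                   what), call. = FALSE)
    }
  }
  g
}

#' Membership weights of the size mixture model
#'
#' Computes the probability that a particle drawn from the blend belongs to
#' each component. By default the per-component size term is
#' \eqn{S_j = \sum_i 1/d_{j,i}^3}, the unweighted sum over the diameters of
#' the classes the component actually occupies (`n_{j,i} > 0`) — the
#' component's own size classes, as an instrument would export them. With
#' `use_frequency_weighting = TRUE` the term is frequency-weighted,
#' \eqn{S_j = \sum_i n_{j,i}/d_{j,i}^3} (an alternative reading of the
#' particle-count derivation; see the methods vignette).
#'
#' @param form A [formulation()].
#' @param components Component library (list of [powder_component()]); all
#'   PSDs must share one grid.
#' @param use_frequency_weighting Use the frequency-weighted size term.
#' @return Object of class `membership_weights`: list with `lambdas`
#'   (summing to 1, one per formulation entry), `abbrs`, `provenance`.
#' @examples
#' # two single-class powders, equal mass, unit density and shape factor:
#' # the 1-um powder contributes 8x the particles of the 2-um powder
#' @export
membership_weights <- function(form, components,
                               use_frequency_weighting = FALSE) {
  stopifnot(inherits(form, "formulation"))
  comps <- resolve_components(form, components)
  check_shared_grid(lapply(comps, `[[`, "psd"), "PSD")
  if (sum(form$mass_fractions) <= 0) {
    stop("all mass fractions are zero", call. = FALSE)
  }
  raw <- vapply(seq_along(comps), function(j) {
    cc <- comps[[j]]
    d <- cc$psd$grid$midpoints
    if (any(d <= 0)) stop("class diameters must be positive", call. = FALSE)
    s_j <- if (use_frequency_weighting) {
      sum(cc$psd$frequencies / d^3)
    } else {
      sum(1 / d[cc$psd$frequencies > 0]^3)
    }
    form$mass_fractions[j] / (cc$true_density * cc$shape_factor) * s_j
  }, 0)
  structure(list(lambdas = raw / sum(raw),
                 abbrs = form$component_abbrs,
                 provenance = "size_model"),
            class = "membership_weights")
}

#' @export
print.membership_weights <- function(x, ...) {
  cat(sprintf("<membership_weights> (%s)\n", x$provenance))
  for (i in seq_along(x$lambdas)) {
    cat(sprintf("  %-10s %.4f\n", x$abbrs[i], x$lambdas[i]))
  }
  invisible(x)
}

#' Predict a blend's number-based particle size distribution
#'
#' Convex combination of the component PSDs with the probabilistic
#' membership weights.
#'
#' @inheritParams membership_weights
#' @return A number-based size [freq_dist()] on the shared component grid.
#' @export
mix_size_distribution <- function(form, components,
                                  use_frequency_weighting = FALSE) {
  comps <- resolve_components(form, components)
  grid <- check_shared_grid(lapply(comps, `[[`, "psd"), "PSD")
  w <- membership_weights(form, components, use_frequency_weighting)$lambdas
  f <- Reduce(`+`, Map(function(lam, cc) lam * cc$psd$frequencies, w, comps))
  freq_dist(grid, f, basis = "number")
}

#' Predict a blend's aspect-ratio distribution
#'
#' Mixes the component ARDs with weights proportional to mass fraction over
#' true density, \eqn{w_j \propto C_j/\rho_{t,j}}, normalized so the result
#' is again a frequency distribution.
#'
#' @inheritParams membership_weights
#' @return A number-based aspect-ratio [freq_dist()].
#' @export
mix_shape_distribution <- function(form, components) {
  comps <- resolve_components(form, components)
  grid <- check_shared_grid(lapply(comps, `[[`, "ard"), "ARD")
  rho <- vapply(comps, `[[`, 0, "true_density")
  if (any(rho <= 0)) stop("true densities must be positive", call. = FALSE)
  w <- form$mass_fractions / rho
  w <- w / sum(w)
  f <- Reduce(`+`, Map(function(wi, cc) wi * cc$ard$frequencies, w, comps))
  freq_dist(grid, f, basis = "number")
}

#' Mass-weighted average-of-percentiles baseline
#'
#' The classic comparator to the probabilistic model: the blend percentile
#' is estimated as the mass-weighted average of the components' own
#' percentiles, \eqn{\sum_j C_j D_q^{(j)}}.
#'
#' @inheritParams membership_weights
#' @param q Percentile fraction in (0, 1); vectorized.
#' @param which `"psd"` or `"ard"`.
#' @return Percentile estimate(s) in the grid's units.
#' @export
baseline_percentile_mixture <- function(form, components, q, which = c("psd", "ard")) {
  which <- match.arg(which)
  comps <- resolve_components(form, components)
  per <- vapply(comps, function(cc) distribution_percentile(cc[[which]], q),
                numeric(length(q)))
  per <- matrix(per, nrow = length(q))
  as.numeric(per %*% form$mass_fractions)
}

#' Fit shape correction factors to a measured blend PSD
#'
#' Optimises the correction (shape) factors phi of the named free
#' components by Levenberg-Marquardt least squares, minimising the RMSE
#' between the model-predicted and measured number-based PSD. All other
#' components keep phi = 1 (or their stored value). Factors are kept
#' positive through a log parameterization, started at phi = 1.
#'
#' @param measured_mix Measured number-based size [freq_dist()] on the same
#'   grid as the component PSDs.
#' @param form A [formulation()].
#' @param components Component library.
#' @param free_components Character vector of component abbreviations whose
#'   phi is optimised; must be part of the formulation.
#' @param control Passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `shape_fit`: `fitted_factors` (named), `rmse`,
#'   `n_iterations`, `converged`, and the fitted mixture distribution.
#' @export
fit_shape_correction <- function(measured_mix, form, components,
                                 free_components,
                                 control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(measured_mix, "freq_dist"))
  comps <- resolve_components(form, components)
  grid <- check_shared_grid(c(list(measured_mix), lapply(comps, `[[`, "psd")),
                            "PSD")
  free_components <- as.character(free_components)
  if (!all(free_components %in% form$component_abbrs)) {
    stop("free_components must be component abbreviations of the formulation",
         call. = FALSE)
  }
  free_idx <- match(free_components, form$component_abbrs)

  with_phi <- function(log_phi) {
    comps2 <- comps
    for (k in seq_along(free_idx)) {
      comps2[[free_idx[k]]]$shape_factor <- exp(log_phi[k])
    }
    mix_size_distribution(form, comps2)
  }
  residuals_fn <- function(log_phi) {
    with_phi(log_phi)$frequencies - measured_mix$frequencies
  }

  fit <- minpack.lm::nls.lm(par = rep(0, length(free_idx)), fn = residuals_fn,
                            control = control)
  phi <- exp(fit$par)
  names(phi) <- free_components
  converged <- fit$info %in% 1:4
  structure(list(fitted_factors = phi,
                 rmse = sqrt(mean(fit$fvec^2)),
                 n_iterations = fit$niter,
                 converged = converged,
                 fitted_mix = with_phi(fit$par),
                 grid = grid),
            class = "shape_fit")
}

#' @export
print.shape_fit <- function(x, ...) {
  cat("<shape_fit> Levenberg-Marquardt shape-correction fit\n")
  for (nm in names(x$fitted_factors)) {
    cat(sprintf("  phi[%s] = %.5g\n", nm, x$fitted_factors[[nm]]))
  }
  cat(sprintf("  RMSE = %.3e (frequency units), %d iterations, converged: %s\n",
              x$rmse, x$n_iterations, x$converged))
  invisible(x)
}
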