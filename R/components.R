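# Raw materials, formulations and flow measurements ------------------------

#' Construct a raw-material component
#'
#' Bundles one raw material's characterisation: true and bulk density
#' (g/cm3), its number-based particle size distribution, its number-based
#' aspect-ratio distribution, and the shape correction factor used by the
#' probabilistic size mixture model (default 1, i.e. spherical-equivalent).
#'
#' @param name Full component name.
#' @param abbreviation Short code used in formulation tables.
#' @param role One of `"api"`, `"filler"`, `"disintegrant"`, `"lubricant"`,
#'   `"other"`.
#' @param true_density True (skeletal) density in g/cm3.
#' @param bulk_density Poured bulk density in g/cm3; must not exceed
#'   `true_density`.
#' @param psd Number-based size [freq_dist()].
#' @param ard Number-based aspect-ratio [freq_dist()].
#' @param shape_factor Positive correction factor for non-spherical
#'   particles in the size mixture model.
#' @return An object of class `powder_component`.
#' @export
powder_component <- function(name, abbreviation = name,
                             role = c("other", "api", "filler",
                                      "disintegrant", "lubricant"),
                             true_density, bulk_density, psd, ard,
                             shape_factor = 1) {
  role <- match.arg(role)
  stopifnot(inherits(psd, "freq_dist"), inherits(ard, "freq_dist"))
  if (psd$grid$kind != "size" || psd$basis != "number") {
    stop("component psd must be a number-based size distribution", call. = FALSE)
  }
  if (ard$grid$kind != "aspect_ratio") {
    stop("component ard must be an aspect-ratio distribution", call. = FALSE)
  }
  if (!is.finite(true_density) || !is.finite(bulk_density) ||
      bulk_density <= 0 || true_density < bulk_density) {
    stop(sprintf(
      "component '%s': densities must satisfy true_density >= bulk_density > 0 (got %.4g, %.4g)",
      name, true_density, bulk_density), call. = FALSE)
  }
  if (!is.finite(shape_factor) || shape_factor <= 0) {
    stop(sprintf("component '%s': shape_factor must be positive", name),
         call. = FALSE)
  }
  structure(list(name = name, abbreviation = abbreviation, role = role,
                 true_density = true_density, bulk_density = bulk_density,
                 psd = psd, ard = ard, shape_factor = shape_factor),
            class = "powder_component")
}

#' @export
print.powder_component <- function(x, ...) {
  cat(sprintf("<powder_component> %s (%s, %s)\n", x$name, x$abbreviation, x$role))
  cat(sprintf("  true density %.3f g/cm3, bulk density %.3f g/cm3, phi = %.3g\n",
              x$true_density, x$bulk_density, x$shape_factor))
  cat(sprintf("  PSD: %d classes; ARD: %d classes\n",
              n_classes(x$psd), n_classes(x$ard)))
  invisible(x)
}

#' Construct a formulation
#'
#' A blend recipe: mass fractions over K components. Fractions must be
#' non-negative and sum to one.
#'
#' @param blend_code Unique blend identifier.
#' @param component_abbrs Character vector of component abbreviations.
#' @param mass_fractions Numeric mass fractions, same length, summing to 1.
#' @param api_label API identity of the blend used for leave-API-out
#'   cross-validation; `"placebo"` for API-free blends.
#' @return An object of class `formulation`.
#' @export
formulation <- function(blend_code, component_abbrs, mass_fractions,
                        api_label = "placebo") {
  component_abbrs <- as.character(component_abbrs)
  mass_fractions <- as.numeric(mass_fractions)
  if (length(component_abbrs) != length(mass_fractions) ||
      length(component_abbrs) < 1L) {
    stop("component_abbrs and mass_fractions must be non-empty and aligned",
         call. = FALSE)
  }
  if (anyNA(mass_fractions) || any(mass_fractions < 0)) {
    stop(sprintf("blend '%s': mass fractions must be non-negative", blend_code),
         call. = FALSE)
  }
  s <- sum(mass_fractions)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("blend '%s': mass fractions sum to %.10g, expected 1",
                 blend_code, s), call. = FALSE)
  }
  if (anyDuplicated(component_abbrs)) {
    stop(sprintf("blend '%s': duplicated component abbreviation", blend_code),
         call. = FALSE)
  }
  structure(list(blend_code = as.character(blend_code),
                 api_label = as.character(api_label),
                 component_abbrs = component_abbrs,
                 mass_fractions = mass_fractions),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation> %s (API: %s)\n", x$blend_code, x$api_label))
  for (i in seq_along(x$component_abbrs)) {
    cat(sprintf("  %-10s %6.3f\n", x$component_abbrs[i], x$mass_fractions[i]))
  }
  invisible(x)
}

# Resolve a formulation's components from a named library list; errors on
# unknown abbreviations.
resolve_components <- function(form, components) {
  abbrs <- vapply(components, function(cc) cc$abbreviation, "")
  idx <- match(form$component_abbrs, abbrs)
  if (anyNA(idx)) {
    stop(sprintf("blend '%s': unknown component abbreviation(s): %s",
                 form$blend_code,
                 paste(form$component_abbrs[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  }
  components[idx]
}

#' Construct a flow measurement record
#'
#' One shear-cell measurement: the flow function coefficient (FFC) of a
#' blend at a given consolidation pressure.
#'
#' @param blend_code Blend identifier.
#' @param consolidation_pressure Normal stress during the shear test, kPa.
#' @param ffc Measured flow function coefficient (> 0).
#' @return An object of class `flow_record`.
#' @export
flow_record <- function(blend_code, consolidation_pressure, ffc) {
  if (!is.finite(consolidation_pressure) || consolidation_pressure <= 0) {
    stop("consolidation pressure must be positive", call. = FALSE)
  }
  if (!is.finite(ffc) || ffc <= 0) {
    stop("ffc must be positive", call. = FALSE)
  }
  structure(list(blend_code = as.character(blend_code),
                 consolidation_pressure = consolidation_pressure,
                 ffc = ffc),
            class = "flow_record")
}

#' Predicted bulk properties of one blend
#'
#' Container for the full set of predicted mixture properties of a blend:
#' size and shape distributions, the three densities, and FFC predictions
#' (with intervals) keyed by consolidation pressure.
#'
#' @param blend_code Blend identifier.
#' @param psd,ard Predicted number-based distributions.
#' @param true_density,bulk_density Predicted densities, g/cm3 (> 0).
#' @param tapped_density Predicted tapped density, g/cm3, or `NA` if no
#'   tapped-density model was applied.
#' @param ffc_by_pressure Data frame with columns `pressure_kpa`, `ffc`
#'   and optionally `lower`, `upper`, `rsd`; may be `NULL`.
#' @return An object of class `mixture_properties`.
#' @export
mixture_properties <- function(blend_code, psd, ard, true_density,
                               bulk_density, tapped_density = NA_real_,
                               ffc_by_pressure = NULL) {
  for (dn in c("true_density", "bulk_density")) {
    v <- get(dn)
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("%s must be positive", dn), call. = FALSE)
    }
  }
  if (!is.na(tapped_density) && tapped_density <= 0) {
    stop("tapped_density must be positive", call. = FALSE)
  }
  structure(list(blend_code = as.character(blend_code), psd = psd, ard = ard,
                 true_density = true_density, bulk_density = bulk_density,
                 tapped_density = tapped_density,
                 ffc_by_pressure = ffc_by_pressure),
            class = "mixture_properties")
}

#' @export
print.mixture_properties <- function(x, ...) {
  cat(sprintf("<mixture_properties> blend %s\n", x$blend_code))
  cat(sprintf("  true %.3f  bulk %.3f  tapped %s g/cm3\n",
              x$true_density, x$bulk_density,
              if (is.na(x$tapped_density)) "--" else sprintf("%.3f", x$tapped_density)))
  cat(sprintf("  PSD D50 = %.4g um, ARD D50 = %.3g\n",
              distribution_percentile(x$psd, 0.5),
              distribution_percentile(x$ard, 0.5)))
  if (!is.null(x$ffc_by_pressure)) {
    cat(sprintf("  FFC at %d pressure(s): %s\n",
                nrow(x$ffc_by_pressure),
                paste(sprintf("%.2f", x$ffc_by_pressure$ffc), collapse = ", ")))
  }
  invisible(x)
}
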