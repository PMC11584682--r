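# Synthetic blend data generator -------------------------------------------
#
# Emulates a raw-material characterisation campaign and a blend dataset so
# the whole pipeline can be exercised without measured data: unimodal
# log-normal-like number-based PSDs on a log-spaced 1001-class grid
# (0.5-500 um), beta-shaped aspect-ratio distributions on (0, 1],
# densities in the ranges typical of pharmaceutical powders (true
# 1.29-1.97 g/cm3, bulk 0.33-0.69 g/cm3), and shear tests at five
# consolidation pressures between 0.79 and 13.26 kPa.
#
# Mixture ground truths (PSD, ARD, densities) are produced by this
# package's own forward models with known shape factors, so parameter- and
# regression-recovery tests are exact by construction. Tapped density and
# FFC have no analytic truth; they are generated by declared smooth
# response models (see generate_blend_dataset) whose only contract is
# smoothness, positivity and coverage of all three flow classes.

#' Configuration for the synthetic data generator
#'
#' @param seed Integer master seed; every random draw derives from it.
#' @param n_components Number of raw materials (first `n_api` are APIs,
#'   the rest fillers).
#' @param n_api Number of API components.
#' @param n_blends Number of blends in the dataset.
#' @param grid Size [class_grid()] for PSDs.
#' @param ar_grid Aspect-ratio [class_grid()] for ARDs.
#' @param psd_meanlog_range,psd_sdlog_range Ranges of the log-normal PSD
#'   parameters (sizes in um).
#' @param ard_mean_range,ard_conc_range Ranges of the beta-distributed
#'   ARD's mean and concentration.
#' @param true_density_range,bulk_density_range Density ranges, g/cm3.
#' @param pressures Consolidation pressures (kPa) applied to every blend.
#' @param snr Signal-to-noise ratio (sd of the noise = sd of the true FFC
#'   response divided by `snr`).
#' @param tapped_slope Slope `a` of the tapped-density response
#'   denominator (per um of D50).
#' @param tapped_noise_sd Noise sd inside the tapped-density denominator.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_components = 8L, n_api = 4L,
                             n_blends = 50L,
                             grid = default_size_grid(),
                             ar_grid = default_ar_grid(),
                             psd_meanlog_range = log(c(5, 60)),
                             psd_sdlog_range = c(0.4, 0.9),
                             ard_mean_range = c(0.45, 0.85),
                             ard_conc_range = c(8, 30),
                             true_density_range = c(1.29, 1.97),
                             bulk_density_range = c(0.33, 0.69),
                             pressures = seq(0.79, 13.26, length.out = 5),
                             snr = 5,
                             tapped_slope = 0.002,
                             tapped_noise_sd = 0.01) {
  stopifnot(n_components >= 2L, n_api >= 1L, n_api < n_components,
            all(pressures > 0), !is.unsorted(pressures),
            true_density_range[1] > 0, bulk_density_range[1] > 0,
            bulk_density_range[2] < true_density_range[1],
            snr > 0)
  structure(as.list(environment()), class = "generator_config")
}

# per-entity seed derived from the master seed, kept inside 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% (.Machine$integer.max - 1))
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Generate one synthetic raw-material component
#'
#' Log-normal number-based PSD discretized on the configured grid (bin
#' masses from the distribution function over the class edges), beta-shaped
#' ARD, densities drawn uniformly in their ranges. Deterministic given
#' `(config, index)`.
#'
#' @param config A [generator_config()].
#' @param index Component index (1-based); indices `1..n_api` get role
#'   `"api"`, the rest `"filler"`.
#' @return A [powder_component()].
#' @export
generate_component <- function(config, index) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(config$seed, index))
  meanlog <- runif1(config$psd_meanlog_range)
  sdlog <- runif1(config$psd_sdlog_range)
  edges <- grid_edges(config$grid)
  p <- diff(stats::plnorm(edges, meanlog, sdlog))
  psd <- freq_dist(config$grid, p / sum(p), basis = "number")

  m <- runif1(config$ard_mean_range)
  k <- runif1(config$ard_conc_range)
  ar_edges <- grid_edges(config$ar_grid)
  q <- diff(stats::pbeta(pmin(ar_edges, 1), m * k, (1 - m) * k))
  ard <- freq_dist(config$ar_grid, q / sum(q), basis = "number")

  is_api <- index <= config$n_api
  powder_component(
    name = if (is_api) paste0("API", index) else paste0("Filler", index - config$n_api),
    abbreviation = if (is_api) paste0("API", index) else paste0("FIL", index - config$n_api),
    role = if (is_api) "api" else "filler",
    true_density = runif1(config$true_density_range),
    bulk_density = runif1(config$bulk_density_range),
    psd = psd, ard = ard, shape_factor = 1)
}

# declared smooth FFC response: increases with blend coarseness (D50),
# consolidation pressure and packing ratio rho_b/rho_t; spans the
# cohesive (<4), easy-flowing (4-10) and free-flowing (>=10) classes over
# the default configuration's input ranges
ffc_response <- function(d50, pressure, rho_t, rho_b) {
  1.2 * sqrt(d50) + 1.1 * pressure + 12 * (rho_b / rho_t) - 8.5
}

# declared tapped-density response: tapping densifies the bed by a factor
# that shrinks with particle size (coarser powders pack closer to their
# poured state)
tapped_response <- function(bulk, d50, slope, eps = 0) {
  bulk / (0.8 + slope * d50 + eps)
}

#' Generate a complete synthetic blend dataset
#'
#' Draws components, composes formulations (placebo or one API at 5-50 %
#' drug loading plus fillers), computes ground-truth mixture PSD/ARD and
#' densities with this package's forward models (shape factors known), and
#' generates tapped-density and FFC responses from the declared smooth
#' response models plus homoscedastic noise. The FFC noise sd is set to
#' `sd(true response) / snr`.
#'
#' @param config A [generator_config()].
#' @return List with `components`, `formulations`, `mixtures` (ground-truth
#'   [mixture_properties()] incl. tapped density), `flow` (data frame:
#'   `blend_code`, `api_label`, `pressure_kpa`, `ffc`, `ffc_true`), and
#'   `manifest` recording every generation parameter.
#' @export
generate_blend_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_blends < 2L) stop("need at least 2 blends", call. = FALSE)
  components <- lapply(seq_len(config$n_components), generate_component,
                       config = config)
  abbrs <- vapply(components, `[[`, "", "abbreviation")
  api_abbrs <- abbrs[seq_len(config$n_api)]
  fil_abbrs <- abbrs[-seq_len(config$n_api)]

  set.seed(derive_seed(config$seed, 10000L))
  formulations <- lapply(seq_len(config$n_blends), function(b) {
    api_label <- c("placebo", api_abbrs)[(b - 1L) %% (config$n_api + 1L) + 1L]
    n_fil <- sample(2:min(3L, length(fil_abbrs)), 1)
    fils <- sample(fil_abbrs, n_fil)
    if (api_label == "placebo") {
      w <- stats::runif(n_fil, 0.2, 1)
      formulation(sprintf("BLD%03d", b), fils, w / sum(w), api_label = "placebo")
    } else {
      c_api <- stats::runif(1, 0.05, 0.5)
      w <- stats::runif(n_fil, 0.2, 1)
      formulation(sprintf("BLD%03d", b), c(api_label, fils),
                  c(c_api, (1 - c_api) * w / sum(w)), api_label = api_label)
    }
  })

  mix_raw <- lapply(formulations, function(f) {
    psd <- mix_size_distribution(f, components)
    list(form = f, psd = psd,
         ard = mix_shape_distribution(f, components),
         rho_t = mix_true_density(f, components, "harmonic"),
         rho_b = mix_bulk_density(f, components, "mass_weighted"),
         d50 = distribution_percentile(psd, 0.5))
  })

  set.seed(derive_seed(config$seed, 20000L))
  # tapped density with noise in the packing denominator
  tapped <- vapply(mix_raw, function(m) {
    tapped_response(m$rho_b, m$d50, config$tapped_slope,
                    stats::rnorm(1, 0, config$tapped_noise_sd))
  }, 0)

  grid_df <- expand.grid(blend = seq_along(mix_raw),
                         pressure = config$pressures)
  grid_df <- grid_df[order(grid_df$blend, grid_df$pressure), ]
  ffc_true <- mapply(function(b, p) {
    m <- mix_raw[[b]]
    ffc_response(m$d50, p, m$rho_t, m$rho_b)
  }, grid_df$blend, grid_df$pressure)
  noise_sd <- stats::sd(ffc_true) / config$snr
  ffc_obs <- pmax(ffc_true + stats::rnorm(length(ffc_true), 0, noise_sd), 0.3)

  flow <- data.frame(
    blend_code = vapply(mix_raw[grid_df$blend], function(m) m$form$blend_code, ""),
    api_label = vapply(mix_raw[grid_df$blend], function(m) m$form$api_label, ""),
    pressure_kpa = grid_df$pressure,
    ffc = ffc_obs, ffc_true = ffc_true)
  rownames(flow) <- NULL

  mixtures <- lapply(seq_along(mix_raw), function(i) {
    m <- mix_raw[[i]]
    fb <- flow[flow$blend_code == m$form$blend_code,
               c("pressure_kpa", "ffc"), drop = FALSE]
    rownames(fb) <- NULL
    mixture_properties(m$form$blend_code, psd = m$psd, ard = m$ard,
                       true_density = m$rho_t, bulk_density = m$rho_b,
                       tapped_density = tapped[i], ffc_by_pressure = fb)
  })

  list(components = components, formulations = formulations,
       mixtures = mixtures, flow = flow,
       manifest = list(seed = config$seed, n_components = config$n_components,
                       n_api = config$n_api, n_blends = config$n_blends,
                       n_classes = n_classes(config$grid),
                       pressures = config$pressures, snr = config$snr,
                       ffc_noise_sd = noise_sd,
                       tapped_slope = config$tapped_slope,
                       tapped_noise_sd = config$tapped_noise_sd))
}
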