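# Small in-code fixtures shared across the suite ---------------------------

# a component on an explicit tiny size grid, with a flat ARD on 3 classes
tiny_component <- function(abbr, midpoints, frequencies, true_density = 1,
                           bulk_density = 0.5, shape_factor = 1,
                           role = "other") {
  g <- class_grid(midpoints, "size")
  arg <- class_grid(c(0.25, 0.5, 0.75), "aspect_ratio")
  powder_component(name = abbr, abbreviation = abbr, role = role,
                   true_density = true_density, bulk_density = bulk_density,
                   psd = freq_dist(g, frequencies),
                   ard = freq_dist(arg, c(1, 1, 1) / 3),
                   shape_factor = shape_factor)
}

# the canonical hand-oracle pair: two single-class powders at 1 and 2 um
# on a shared two-class grid
single_class_pair <- function(rho = c(1, 1), phi = c(1, 1)) {
  list(tiny_component("A", c(1, 2), c(1, 0), true_density = rho[1],
                      shape_factor = phi[1]),
       tiny_component("B", c(1, 2), c(0, 1), true_density = rho[2],
                      shape_factor = phi[2]))
}

# random component set on one shared log-spaced grid
random_components <- function(n, n_cls = 15, seed = 1) {
  set.seed(seed)
  g <- class_grid(exp(seq(log(1), log(100), length.out = n_cls)), "size")
  arg <- class_grid(seq(0.1, 1, length.out = 5), "aspect_ratio")
  lapply(seq_len(n), function(i) {
    f <- stats::runif(n_cls)
    fa <- stats::runif(5)
    rt <- stats::runif(1, 1.2, 2)
    powder_component(name = paste0("C", i), abbreviation = paste0("C", i),
                     true_density = rt,
                     bulk_density = stats::runif(1, 0.3, min(0.7, rt)),
                     psd = freq_dist(g, f / sum(f)),
                     ard = freq_dist(arg, fa / sum(fa)),
                     shape_factor = stats::runif(1, 0.5, 2))
  })
}

# random formulation over a component set
random_formulation <- function(components, code = "BLD", k = NULL) {
  n <- length(components)
  if (is.null(k)) k <- sample(seq_len(n), 1)
  pick <- sample(n, k)
  w <- stats::rexp(k)
  formulation(code, vapply(components[pick], `[[`, "", "abbreviation"),
              w / sum(w))
}

# independent brute-force percentile: explicit scan of the piecewise-linear
# mid-mass cumulative curve, no shared code with distribution_percentile()
brute_force_percentile <- function(midpoints, frequencies, q) {
  keep <- frequencies > 0
  x <- midpoints[keep]
  f <- frequencies[keep] / sum(frequencies[keep])
  if (length(x) == 1L) return(x)
  cdf <- numeric(length(x))
  acc <- 0
  for (i in seq_along(x)) {
    cdf[i] <- acc + f[i] / 2
    acc <- acc + f[i]
  }
  if (q <= cdf[1]) return(x[1])
  if (q >= cdf[length(x)]) return(x[length(x)])
  for (i in seq_len(length(x) - 1L)) {
    if (q >= cdf[i] && q <= cdf[i + 1L]) {
      return(x[i] + (q - cdf[i]) / (cdf[i + 1L] - cdf[i]) * (x[i + 1L] - x[i]))
    }
  }
  stop("unreachable")
}
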