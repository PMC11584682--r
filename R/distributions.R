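# Class grids and discrete frequency distributions -------------------------
#
# Particle size distributions (PSD) and aspect-ratio distributions (ARD)
# are represented as normalized frequencies over a fixed grid of class
# midpoints: micrometres for size, dimensionless values in (0, 1] for
# aspect ratio. Instruments conventionally export 1001 classes.

#' Construct a class grid
#'
#' A class grid holds the ordered midpoints of the discrete classes on which
#' a frequency distribution is tabulated. Size grids are in micrometres;
#' aspect-ratio grids are dimensionless with all midpoints in (0, 1].
#'
#' @param midpoints Strictly increasing vector of positive class midpoints.
#' @param kind `"size"` (micrometres) or `"aspect_ratio"`.
#' @return An object of class `class_grid`.
#' @examples
#' g <- class_grid(c(1, 2, 5, 10), "size")
#' n_classes(g)
#' @export
class_grid <- function(midpoints, kind = c("size", "aspect_ratio")) {
  kind <- match.arg(kind)
  midpoints <- as.numeric(midpoints)
  if (length(midpoints) < 1L || anyNA(midpoints)) {
    stop("class grid midpoints must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(midpoints <= 0)) {
    stop("class grid midpoints must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(midpoints, strictly = TRUE)) {
    stop("class grid midpoints must be strictly increasing", call. = FALSE)
  }
  if (kind == "aspect_ratio" && any(midpoints > 1)) {
    stop("aspect-ratio midpoints must lie in (0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, midpoints = midpoints),
            class = "class_grid")
}

#' Default logarithmically spaced size grid
#'
#' Log-spaced class midpoints emulating optical-microscopy size classing,
#' by convention 1001 classes over 0.5 to 500 micrometres.
#'
#' @param n_classes Number of classes.
#' @param from,to Range of midpoints in micrometres.
#' @return A size-kind [class_grid()].
#' @export
default_size_grid <- function(n_classes = 1001L, from = 0.5, to = 500) {
  class_grid(exp(seq(log(from), log(to), length.out = n_classes)), "size")
}

#' Default aspect-ratio grid
#'
#' Evenly spaced aspect-ratio class midpoints on (0, 1].
#'
#' @param n_classes Number of classes.
#' @return An aspect-ratio-kind [class_grid()].
#' @export
default_ar_grid <- function(n_classes = 1001L) {
  class_grid(seq(1 / n_classes, 1, length.out = n_classes), "aspect_ratio")
}

#' Number of classes of a grid or distribution
#' @param x A `class_grid` or `freq_dist`.
#' @return Integer class count.
#' @export
n_classes <- function(x) {
  if (inherits(x, "freq_dist")) x <- x$grid
  length(x$midpoints)
}

#' @export
print.class_grid <- function(x, ...) {
  cat(sprintf("<class_grid> %s, %d classes, midpoints %.4g .. %.4g%s\n",
              x$kind, n_classes(x), min(x$midpoints), max(x$midpoints),
              if (x$kind == "size") " um" else ""))
  invisible(x)
}

# Class edges implied by midpoints: interior edges halfway between adjacent
# midpoints, outer edges extrapolated symmetrically (floored at 0 on the
# left so size classes stay positive).
grid_edges <- function(grid) {
  m <- grid$midpoints
  n <- length(m)
  if (n == 1L) {
    h <- max(m[1] * 0.5, .Machine$double.eps)
    return(c(max(m[1] - h, 0), m[1] + h))
  }
  inner <- (m[-n] + m[-1]) / 2
  c(max(m[1] - (inner[1] - m[1]), 0), inner, m[n] + (m[n] - inner[n - 1L]))
}

#' Construct a frequency distribution
#'
#' Frequencies are validated as non-negative and renormalized to sum to one.
#' Deviations of the raw sum from one of up to `1e-3` are treated as
#' instrument rounding and silently renormalized; larger deviations are a
#' data error and refused.
#'
#' @param grid A [class_grid()].
#' @param frequencies Non-negative frequencies, one per grid class.
#' @param basis `"number"` (frequencies count particles) or `"volume"`
#'   (each particle weighted by its volume).
#' @param renorm_tol Maximum tolerated deviation of `sum(frequencies)` from
#'   one before construction is refused.
#' @return An object of class `freq_dist` with components `grid`,
#'   `frequencies` (summing to one) and `basis`.
#' @examples
#' g <- class_grid(c(1, 2), "size")
#' d <- freq_dist(g, c(0.5, 0.5))
#' sum(d$frequencies)
#' @export
freq_dist <- function(grid, frequencies, basis = c("number", "volume"),
                      renorm_tol = 1e-3) {
  basis <- match.arg(basis)
  stopifnot(inherits(grid, "class_grid"))
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != n_classes(grid)) {
    stop(sprintf("expected %d frequencies, got %d",
                 n_classes(grid), length(frequencies)), call. = FALSE)
  }
  if (anyNA(frequencies) || any(frequencies < 0)) {
    stop("frequencies must be non-negative and finite", call. = FALSE)
  }
  s <- sum(frequencies)
  if (s <= 0) stop("frequencies sum to zero", call. = FALSE)
  if (abs(s - 1) >= renorm_tol) {
    stop(sprintf(
      "frequencies sum to %.6g; deviation from 1 exceeds the renormalization tolerance %g",
      s, renorm_tol), call. = FALSE)
  }
  structure(list(grid = grid, frequencies = frequencies / s, basis = basis),
            class = "freq_dist")
}

#' @export
print.freq_dist <- function(x, ...) {
  cat(sprintf("<freq_dist> %s-based over %d %s classes\n",
              x$basis, n_classes(x), x$grid$kind))
  qs <- vapply(c(0.1, 0.5, 0.9), function(q) distribution_percentile(x, q), 0)
  cat(sprintf("  D10 = %.4g  D50 = %.4g  D90 = %.4g\n", qs[1], qs[2], qs[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  a$kind == b$kind && length(a$midpoints) == length(b$midpoints) &&
    all(a$midpoints == b$midpoints)
}

#' Regrid a frequency distribution onto a new class grid
#'
#' The cumulative distribution is evaluated at the source class edges,
#' linearly interpolated onto the target class edges, and differenced. Mass
#' falling outside the target grid's span is clamped into the extreme
#' classes so the result still sums to one.
#'
#' @param dist A [freq_dist()].
#' @param target A [class_grid()] of the same kind as `dist$grid`.
#' @return A `freq_dist` on `target`.
#' @export
regrid <- function(dist, target) {
  stopifnot(inherits(dist, "freq_dist"), inherits(target, "class_grid"))
  if (dist$grid$kind != target$kind) {
    stop(sprintf("cannot regrid a %s distribution onto a %s grid",
                 dist$grid$kind, target$kind), call. = FALSE)
  }
  if (same_grid(dist$grid, target)) return(dist)
  src_edges <- grid_edges(dist$grid)
  cdf <- c(0, cumsum(dist$frequencies))
  tgt_edges <- grid_edges(target)
  tgt_cdf <- stats::approx(src_edges, cdf, xout = tgt_edges,
                           method = "linear", rule = 2, ties = "ordered")$y
  tgt_cdf <- pmin(pmax(tgt_cdf, 0), 1)
  tgt_cdf <- cummax(tgt_cdf)
  f <- diff(tgt_cdf)
  # clamp out-of-span mass into the boundary classes
  f[1] <- f[1] + tgt_cdf[1]
  f[length(f)] <- f[length(f)] + (1 - tgt_cdf[length(tgt_cdf)])
  freq_dist(target, f, basis = dist$basis)
}

#' Convert between number- and volume-based distributions
#'
#' On a size grid, volume frequencies are proportional to the number
#' frequencies weighted by the cube of the class diameter,
#' \eqn{v_i \propto n_i d_i^3}; the inverse applies weight \eqn{1/d_i^3}.
#' The round trip is the identity to numerical precision.
#'
#' @param dist A size-kind [freq_dist()].
#' @param to Target basis, `"volume"` or `"number"`. Defaults to the basis
#'   `dist` is not currently on.
#' @return A `freq_dist` on the same grid with the requested basis.
#' @examples
#' d <- freq_dist(class_grid(c(1, 2), "size"), c(0.5, 0.5))
#' convert_basis(d)$frequencies  # (1/9, 8/9)
#' @export
convert_basis <- function(dist, to = NULL) {
  stopifnot(inherits(dist, "freq_dist"))
  if (dist$grid$kind != "size") {
    stop("basis conversion is defined for size distributions only", call. = FALSE)
  }
  if (is.null(to)) to <- if (dist$basis == "number") "volume" else "number"
  to <- match.arg(to, c("number", "volume"))
  if (to == dist$basis) return(dist)
  d3 <- dist$grid$midpoints^3
  w <- if (to == "volume") dist$frequencies * d3 else dist$frequencies / d3
  if (sum(w) <= 0) stop("degenerate distribution: zero total after weighting", call. = FALSE)
  freq_dist(dist$grid, w / sum(w), basis = to)
}

#' Percentile of a frequency distribution
#'
#' Linear interpolation of the cumulative curve over class midpoints, using
#' the mid-mass convention: class `i` carries cumulative mass
#' `cumsum(f)[i] - f[i]/2` at its midpoint. Only classes with non-zero
#' frequency act as interpolation nodes, so flat cumulative segments are
#' skipped and queries beyond the first/last node clamp to that node's
#' class value (leftmost/rightmost non-empty class).
#'
#' @param dist A [freq_dist()].
#' @param q Percentile fraction strictly inside (0, 1); vectorized.
#' @return Class value(s) (micrometres or aspect ratio) at the requested
#'   percentile(s).
#' @examples
#' d <- freq_dist(class_grid(c(1, 2), "size"), c(0.5, 0.5))
#' distribution_percentile(d, 0.5)  # 1.5
#' @export
distribution_percentile <- function(dist, q) {
  stopifnot(inherits(dist, "freq_dist"))
  if (any(q <= 0 | q >= 1)) {
    stop("percentile fraction q must lie strictly inside (0, 1)", call. = FALSE)
  }
  f <- dist$frequencies
  keep <- f > 0
  x <- dist$grid$midpoints[keep]
  fk <- f[keep]
  cdf_mid <- cumsum(fk) - fk / 2
  if (length(x) == 1L) return(rep(x, length(q)))
  stats::approx(cdf_mid, x, xout = q, method = "linear", rule = 2,
                ties = "ordered")$y
}
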