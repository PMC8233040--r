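# Coding analysis: lagged Pearson correlation, lagged mutual information
# with fixed equal-width binning, optimal-lag extraction, speed tuning
# curves, active-window presynaptic correlations, and direction metrics.

# Overlapping index pairs for lag l (in samples): x[i] vs y[i + k].
# A positive optimal lag means y leads is NOT the convention here; see
# lagged_correlation for the exact pairing contract.
lag_overlap <- function(n, k) {
  xi <- max(1L, 1L - k):min(n, n - k)
  list(x = xi, y = xi + k)
}

new_lag_similarity <- function(lags, values, kind) {
  opt <- optimal_lag_impl(lags, values)
  structure(list(lags = lags, values = values, kind = kind,
                 optimal_lag = opt$lag, max_value = opt$value),
            class = "lag_similarity")
}

#' @export
print.lag_similarity <- function(x, ...) {
  cat(sprintf("<lag_similarity:%s> %d lags; max = %.4f at lag %g ms\n",
              x$kind, length(x$lags), x$max_value, x$optimal_lag))
  invisible(x)
}

#' Lag-resolved Pearson correlation between two series
#'
#' For each lag `l` (a multiple of `dt`), pairs `x[t]` with `y[t + l]` on
#' the overlapping support and computes the Pearson correlation. A delayed
#' copy `y[t] = x[t - L]` therefore attains its maximum (value 1) at lag
#' `L`; when `x` is a postsynaptic rate and `y` the head speed, a
#' *negative* optimal lag means the rate tracks past speed.
#'
#' @param x,y numeric series on a common uniform grid.
#' @param dt grid step, ms.
#' @param lags lags in ms, each a multiple of `dt` (default -70..70 by 2).
#' @param min_overlap minimum overlapping samples per lag.
#' @return A `lag_similarity` with fields `lags`, `values`, `kind`,
#'   `optimal_lag`, `max_value`; zero-variance overlaps yield `NA` values.
#' @export
lagged_correlation <- function(x, y, dt, lags = seq(-70, 70, by = 2),
                               min_overlap = 100L) {
  n <- length(x)
  stopifnot(length(y) == n)
  ks <- lags / dt
  if (any(abs(ks - round(ks)) > 1e-8)) {
    stop("every lag must be a multiple of dt", call. = FALSE)
  }
  ks <- as.integer(round(ks))
  vals <- vapply(ks, function(k) {
    ov <- lag_overlap(n, k)
    if (length(ov$x) < min_overlap) return(NA_real_)
    xs <- x[ov$x]; ys <- y[ov$y]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1))
  new_lag_similarity(lags, vals, "correlation")
}

# Equal-width discretization over the observed range; returns integer
# codes in 1..bins (constant series map to bin 1).
bin_series <- function(x, bins) {
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(1L, length(x)))
  idx <- floor((x - rng[1L]) / (rng[2L] - rng[1L]) * bins) + 1L
  pmin(idx, bins)
}

# Plug-in MI in bits from two integer code vectors.
mi_from_codes <- function(xi, yi, bins) {
  joint <- tabulate(xi + bins * (yi - 1L), nbins = bins * bins)
  n <- length(xi)
  pj <- joint / n
  px <- tabulate(xi, nbins = bins) / n
  py <- tabulate(yi, nbins = bins) / n
  pprod <- as.numeric(outer(px, py))
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / pprod[nz]))
}

#' Lag-resolved mutual information between two series
#'
#' Each full series is discretized once into `bins` equal-width bins over
#' its observed range; for each lag the plug-in mutual information (bits)
#' between the overlapping code vectors is computed. Lag pairing matches
#' [lagged_correlation()].
#'
#' @inheritParams lagged_correlation
#' @param bins number of bins per series (default 40).
#' @return A `lag_similarity` with `kind = "mutual_information"`.
#' @export
lagged_mutual_information <- function(x, y, dt, lags = seq(-70, 70, by = 2),
                                      bins = 40L, min_overlap = 100L) {
  n <- length(x)
  stopifnot(length(y) == n)
  ks <- lags / dt
  if (any(abs(ks - round(ks)) > 1e-8)) {
    stop("every lag must be a multiple of dt", call. = FALSE)
  }
  ks <- as.integer(round(ks))
  xi <- bin_series(x, bins)
  yi <- bin_series(y, bins)
  vals <- vapply(ks, function(k) {
    ov <- lag_overlap(n, k)
    if (length(ov$x) < min_overlap) return(NA_real_)
    mi_from_codes(xi[ov$x], yi[ov$y], bins)
  }, numeric(1))
  new_lag_similarity(lags, vals, "mutual_information")
}

optimal_lag_impl <- function(lags, values) {
  ok <- which(!is.na(values))
  if (!length(ok)) return(list(lag = NA_real_, value = NA_real_))
  best <- ok[values[ok] >= max(values[ok]) - 1e-15]
  best <- best[order(abs(lags[best]), lags[best])][1L]
  list(lag = lags[best], value = values[best])
}

#' Optimal lag of a lag-similarity curve
#'
#' Argmax over lags; ties broken toward the smallest `|lag|`, then the
#' negative lag.
#'
#' @param sim a `lag_similarity`.
#' @return List with `lag` (ms) and `value`.
#' @export
optimal_lag <- function(sim) {
  stopifnot(inherits(sim, "lag_similarity"))
  res <- optimal_lag_impl(sim$lags, sim$values)
  if (is.na(res$lag)) stop("no lag has a defined similarity value",
                           call. = FALSE)
  res
}

#' Firing rate binned by angular head speed (or signed velocity)
#'
#' Per-bin mean and standard deviation of the rate, binned by speed. Pass
#' a signed angular velocity series to obtain the signed-AHV tuning curve;
#' symmetry of that curve about 0 rad/s is the hallmark of a pure speed
#' (not direction-of-turn) code.
#'
#' @param rate firing-rate series, Hz.
#' @param speed angular speed (rad/s) or signed velocity series, same grid.
#' @param bin_edges numeric bin edges; default 16 equal-width bins over
#'   the observed range.
#' @param nbins number of bins used when `bin_edges` is `NULL`.
#' @return Data frame (class `speed_tuning`) with `bin_lo`, `bin_hi`,
#'   `bin_mid`, `mean_hz`, `sd_hz`, `n`; empty bins are kept with
#'   `n = 0` and `NA` statistics.
#' @export
speed_tuning_curve <- function(rate, speed, bin_edges = NULL, nbins = 16L) {
  stopifnot(length(rate) == length(speed))
  if (is.null(bin_edges)) {
    bin_edges <- seq(min(speed), max(speed), length.out = nbins + 1L)
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(speed, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  mean_hz <- sd_hz <- rep(NA_real_, nb)
  cnt <- tabulate(idx, nbins = nb)
  for (b in which(cnt > 0L)) {
    rb <- rate[idx == b]
    mean_hz[b] <- mean(rb)
    sd_hz[b] <- if (length(rb) > 1L) stats::sd(rb) else 0
  }
  out <- data.frame(bin_lo = bin_edges[-(nb + 1L)], bin_hi = bin_edges[-1L],
                    bin_mid = (bin_edges[-(nb + 1L)] + bin_edges[-1L]) / 2,
                    mean_hz = mean_hz, sd_hz = sd_hz, n = cnt)
  class(out) <- c("speed_tuning", "data.frame")
  out
}

#' Presynaptic rate vs speed correlation in active windows
#'
#' For each HD cell, the Pearson correlation between its firing rate and
#' angular head speed restricted to samples where the cell fires above
#' `threshold` Hz. Cells never active, or with zero variance in the active
#' window, are excluded (`NA`).
#'
#' @param rates matrix (cells x time) or list of rate series, Hz.
#' @param speed angular speed series, rad/s, on the same grid.
#' @param threshold activity threshold, Hz (default 10).
#' @param min_samples minimum active samples for a defined value.
#' @return List with `values` (per-cell correlations, `NA` when
#'   undefined), `mean` (over defined cells) and `n_excluded`.
#' @export
active_window_correlation <- function(rates, speed, threshold = 10,
                                      min_samples = 100L) {
  if (is.matrix(rates)) rates <- asplit(rates, 1L)
  vals <- unname(vapply(rates, function(r) {
    act <- r > threshold
    if (sum(act) < min_samples) return(NA_real_)
    if (stats::sd(r[act]) == 0 || stats::sd(speed[act]) == 0) {
      return(NA_real_)
    }
    stats::cor(r[act], speed[act])
  }, numeric(1)))
  list(values = vals, mean = mean(vals, na.rm = TRUE),
       n_excluded = sum(is.na(vals)))
}

#' Direction coding of a firing-rate series
#'
#' Mutual information (bits) between the equal-width-binned rate and the
#' wrapped head direction discretized into `bins` bins over `[0, 2*pi)`,
#' plus a circular-linear correlation coefficient (the correlation of the
#' rate with the best-fitting cosine of direction; Mardia's formula),
#' which is seam-independent unlike a raw Pearson correlation with angle.
#'
#' @param rate firing-rate series, Hz.
#' @param theta head-direction series, radians (wrapping is internal).
#' @param bins number of bins for each variable.
#' @return List with `mi_bits` and `circ_lin_corr` (in `[0, 1]`).
#' @export
direction_information <- function(rate, theta, bins = 40L) {
  stopifnot(length(rate) == length(theta))
  th <- wrap_angle(theta)
  ti <- pmin(bins, floor(th / (2 * pi) * bins) + 1L)
  ri <- bin_series(rate, bins)
  mi <- mi_from_codes(ri, as.integer(ti), as.integer(bins))
  rc <- stats::cor(rate, cos(th))
  rs <- stats::cor(rate, sin(th))
  rcs <- stats::cor(cos(th), sin(th))
  r2 <- (rc^2 + rs^2 - 2 * rc * rs * rcs) / (1 - rcs^2)
  list(mi_bits = mi, circ_lin_corr = sqrt(max(0, r2)))
}
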