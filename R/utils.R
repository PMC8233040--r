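# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded draws never perturb unrelated randomness.
#' With `seed = NULL` the code runs against the current RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# One master seed spawns per-unit seeds so results do not depend on the
# order or number of units simulated before a given one.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

#' Unwrap a circular angle series
#'
#' Removes 2*pi jumps so the series becomes continuous; the wrapped view
#' is recovered with [wrap_angle()].
#'
#' @param theta numeric vector of angles in radians.
#' @return Numeric vector, congruent to `theta` modulo 2*pi, with no
#'   step larger than pi between consecutive samples.
#' @export
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1L] + c(0, cumsum(d))
}

#' Wrap angles to [0, 2*pi)
#' @param theta numeric vector of angles in radians.
#' @return Angles reduced modulo 2*pi into `[0, 2*pi)`.
#' @export
wrap_angle <- function(theta) theta %% (2 * pi)

# Trapezoidal integral on a (possibly non-uniform) grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# First-order exponential decay driven by per-bin impulses:
# g[i] = a * g[i-1] + jumps[i], a = exp(-dt/tau). Exact for impulses
# located at bin times.
decay_filter <- function(jumps, dt, tau) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter(jumps, a, method = "recursive"))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
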