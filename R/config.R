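#' Model configuration
#'
#' Bundles the structural settings of the zero-inflated Poisson hidden
#' semi-Markov model: the number of latent states, the (finite) dwell-time
#' support, the base duration density family, and the covariate dimensions.
#'
#' @param M Number of latent states (integer, >= 1). States are ordered by
#'   mean emission intensity via the monotonicity constraints on the emission
#'   coefficients.
#' @param D_max Maximum dwell duration in minutes (integer, >= 1). Dwell
#'   distributions are truncation-renormalized to the support `1..D_max`,
#'   which realizes the finite-support assumption of the model. Default 360
#'   minutes (6 h), which comfortably exceeds plausible single-behaviour bouts
#'   at minute resolution while keeping the recursion cost bounded.
#' @param duration_family Base density family of the dwell-time accelerated
#'   failure time model: `"weibull"` (default) or `"gamma"`. Both are closed
#'   under the AFT time rescaling; each state has its own shape and scale.
#' @param q Dimension of the per-minute treatment covariate vector x
#'   (binary treatment indicator in the motivating crossover study, q = 1).
#' @param p Dimension of the per-minute environmental covariate vector z
#'   (night and weekend indicators in the motivating study, p = 2).
#' @param d Dimension of the per-subject baseline covariate vector W used by
#'   the second-stage population regression (0 when no baseline covariates).
#'
#' @return An object of class `"hsmm_config"`.
#' @export
#' @examples
#' cfg <- model_config(M = 2, D_max = 20, q = 1, p = 0)
#' cfg
model_config <- function(M, D_max = 360L,
                         duration_family = c("weibull", "gamma"),
                         q = 1L, p = 2L, d = 0L) {
  duration_family <- match.arg(duration_family)
  M <- as.integer(M); D_max <- as.integer(D_max)
  q <- as.integer(q); p <- as.integer(p); d <- as.integer(d)
  if (length(M) != 1L || is.na(M) || M < 1L)
    stop("`M` must be a single integer >= 1")
  if (length(D_max) != 1L || is.na(D_max) || D_max < 1L)
    stop("`D_max` must be a single integer >= 1")
  if (any(is.na(c(q, p, d))) || q < 0L || p < 0L || d < 0L)
    stop("covariate dimensions `q`, `p`, `d` must be nonnegative integers")
  structure(list(M = M, D_max = D_max, duration_family = duration_family,
                 q = q, p = p, d = d),
            class = "hsmm_config")
}

#' @export
print.hsmm_config <- function(x, ...) {
  cat(sprintf(
    "ZIP-HSMM configuration: M = %d states, D_max = %d min, %s dwell family, q = %d, p = %d, d = %d\n",
    x$M, x$D_max, x$duration_family, x$q, x$p, x$d))
  invisible(x)
}

# Layout of the unconstrained parameter vector. A single source of truth used
# by to_unconstrained()/from_unconstrained(), the fitter's free-coordinate
# mask, and mirrored (same order) by the C++ objective. Block order:
#   delta (M-1 centered logits; empty when M = 1)
#   b00 (1), b10 (q), gamma0 (p)
#   b0 (M: first value, then log-increments)
#   b1 (M*q: per column, first value then squared increments)
#   gamma (M*p: same scheme)
#   log_shape (M), log_scale (M)
#   c (M*q, column-major), eta (M*p, column-major)
#   trans (M*(M-2)*(q+p) for M >= 3: origin-major, destinations ascending,
#          reference destination (lowest index != origin) omitted; within a
#          destination q treatment coefs then p environment coefs)
param_layout <- function(config) {
  M <- config$M; q <- config$q; p <- config$p
  sizes <- c(delta = if (M > 1L) M - 1L else 0L,
             b00 = 1L, b10 = q, gamma0 = p,
             b0 = M, b1 = M * q, gamma = M * p,
             log_shape = M, log_scale = M,
             c = M * q, eta = M * p,
             trans = if (M >= 3L) M * (M - 2L) * (q + p) else 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  idx <- mapply(function(s, e, n) if (n == 0L) integer(0) else s:e,
                starts, ends, sizes, SIMPLIFY = FALSE)
  names(idx) <- names(sizes)
  list(idx = idx, sizes = sizes, length = as.integer(ends[[length(ends)]]))
}

# Reference (zero-coefficient) transition destination for origin state m.
transition_reference <- function(m) if (m == 1L) 2L else 1L
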