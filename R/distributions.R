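#' Zero-inflated Poisson log probability mass
#'
#' Log of `p_zero * 1{y = 0} + (1 - p_zero) * lam^y exp(-lam) / y!`, the
#' mixture of a point mass at zero and a Poisson density used for the
#' resting-state emission. All arguments are vectorized with recycling.
#'
#' @param y Nonnegative integer count(s).
#' @param p_zero Zero-inflation weight(s) in `[0, 1]`.
#' @param lam Poisson intensity(ies), `> 0` (`lam = 0` is admitted only
#'   together with `y = 0`).
#' @return Log probability mass, same length as the recycled arguments.
#' @export
#' @examples
#' zip_log_pmf(0, 0.5, 1)          # log(0.5 + 0.5 * exp(-1))
#' zip_log_pmf(3, 0, 2)            # plain Poisson log-pmf
zip_log_pmf <- function(y, p_zero, lam) {
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
    stop("`y` must be nonnegative integer(s)")
  if (any(is.na(p_zero)) || any(p_zero < 0) || any(p_zero > 1))
    stop("`p_zero` must lie in [0, 1]")
  if (any(is.na(lam)) || any(lam < 0))
    stop("`lam` must be nonnegative")
  n <- max(length(y), length(p_zero), length(lam))
  y <- rep_len(y, n); p_zero <- rep_len(p_zero, n); lam <- rep_len(lam, n)
  if (any(lam == 0 & y > 0))
    stop("`lam` = 0 is only admitted with y = 0")
  out <- numeric(n)
  z <- y == 0
  if (any(z)) {
    # log(p0 + (1 - p0) exp(-lam)) via log-sum-exp: robust when both the
    # point-mass weight and the Poisson zero mass underflow
    a <- log(p_zero[z])
    b <- log1p(-p_zero[z]) - lam[z]
    mx <- pmax(a, b)
    out[z] <- ifelse(mx == -Inf, -Inf,
                     mx + log(exp(a - mx) + exp(b - mx)))
  }
  if (any(!z))
    out[!z] <- log1p(-p_zero[!z]) + dpois(y[!z], lam[!z], log = TRUE)
  out
}

#' Per-minute emission parameters for a given state and covariates
#'
#' Evaluates the link models: `lam = exp(b0[m] + b1[m,]'x + gamma[m,]'z)` for
#' every state, and the logistic zero-inflation weight
#' `p_zero = plogis(b00 + b10'x + gamma0'z)` for state 1 only (zero inflation
#' is confined to the resting state; `p_zero = 0` for m >= 2).
#'
#' @param m State index in `1..M`.
#' @param x Treatment covariate vector (length q).
#' @param z Environment covariate vector (length p).
#' @param coef An [emission_coefficients()] object.
#' @return List with elements `p_zero` and `lam`.
#' @export
emission_params <- function(m, x, z, coef) {
  M <- length(coef$b0)
  if (length(m) != 1L || m < 1L || m > M)
    stop(sprintf("state index m = %s out of range 1..%d", paste(m, collapse = ","), M))
  x <- as.numeric(x); z <- as.numeric(z)
  if (length(x) != ncol(coef$b1))
    stop("treatment covariate dimension mismatch")
  if (length(z) != ncol(coef$gamma))
    stop("environment covariate dimension mismatch")
  lam <- exp(coef$b0[m] + sum(coef$b1[m, ] * x) + sum(coef$gamma[m, ] * z))
  p_zero <- if (m == 1L)
    plogis(coef$b00 + sum(coef$b10 * x) + sum(coef$gamma0 * z))
  else 0
  list(p_zero = p_zero, lam = lam)
}

#' Transition probabilities out of a state
#'
#' Multinomial-logit destination probabilities conditional on leaving origin
#' state `m`: entry `l != m` is `exp(d[m,l]'x + rho[m,l]'z)` normalized over
#' the allowed destinations (the reference destination, the lowest index
#' different from `m`, has coefficients fixed at zero); entry `m` is exactly
#' zero since self-transitions are owned by the dwell model.
#'
#' @param m Origin state.
#' @param x,z Covariate vectors at the minute the transition occurs.
#' @param coef A [transition_coefficients()] object.
#' @return Probability vector over destinations `1..M` summing to one.
#' @export
transition_row <- function(m, x, z, coef) {
  M <- if (length(dim(coef$d_coef)) == 3L) dim(coef$d_coef)[1L]
       else dim(coef$rho)[1L]
  if (is.null(M) || M < 2L)
    stop("transitions require M >= 2 states")
  if (length(m) != 1L || m < 1L || m > M) stop("origin state out of range")
  x <- as.numeric(x); z <- as.numeric(z)
  q <- dim(coef$d_coef)[3L]; p <- dim(coef$rho)[3L]
  if (length(x) != q) stop("treatment covariate dimension mismatch")
  if (length(z) != p) stop("environment covariate dimension mismatch")
  logits <- rep(-Inf, M)
  for (l in seq_len(M)[-m]) {
    logits[l] <- (if (q > 0L) sum(coef$d_coef[m, l, ] * x) else 0) +
      (if (p > 0L) sum(coef$rho[m, l, ] * z) else 0)
  }
  mx <- max(logits)
  pr <- exp(logits - mx)
  pr[m] <- 0
  pr / sum(pr)
}

#' Dwell-duration pmf and survivor function
#'
#' Discretizes the accelerated failure time dwell model to integer minutes:
#' with acceleration `a = exp(c[m,]'x + eta[m,]'z)` and base distribution
#' function F (Weibull or gamma with state m's shape and scale), the mass at
#' duration `v` is proportional to `F(a (v + 1)) - F(a v)` (the integral of
#' the rescaled density over `[v, v + 1)`), truncation-renormalized to the
#' support `1..D_max`. The survivor function is `S(v) = sum_{u >= v} pmf(u)`,
#' so `S(1) = 1`; it right-censors the final dwell of a series.
#'
#' @param m State index.
#' @param x,z Covariate vectors at the minute the dwell begins.
#' @param dur A [duration_model()] object.
#' @param config An [model_config()] object (supplies `D_max` and family).
#' @return List with elements `pmf` and `survivor`, each of length `D_max`.
#' @export
#' @examples
#' cfg <- model_config(M = 1, D_max = 50, q = 0, p = 0)
#' dm <- duration_model(shape = 1, scale = 1,
#'                      c = matrix(0, 1, 0), eta = matrix(0, 1, 0))
#' duration_pmf(1, numeric(0), numeric(0), dm, cfg)$pmf[1]  # 1 - exp(-1)
duration_pmf <- function(m, x, z, dur, config) {
  M <- length(dur$shape)
  if (length(m) != 1L || m < 1L || m > M) stop("state index out of range")
  if (!is.finite(dur$shape[m]) || dur$shape[m] <= 0)
    stop("duration shape must be strictly positive")
  if (!is.finite(dur$scale[m]) || dur$scale[m] <= 0)
    stop("duration scale must be strictly positive")
  x <- as.numeric(x); z <- as.numeric(z)
  if (length(x) != ncol(dur$c)) stop("treatment covariate dimension mismatch")
  if (length(z) != ncol(dur$eta)) stop("environment covariate dimension mismatch")
  a <- exp(sum(dur$c[m, ] * x) + sum(dur$eta[m, ] * z))
  D <- config$D_max
  cdf <- switch(config$duration_family,
                weibull = function(t) stats::pweibull(t, dur$shape[m], dur$scale[m]),
                gamma = function(t) stats::pgamma(t, shape = dur$shape[m],
                                                  scale = dur$scale[m]))
  Fv <- cdf(a * seq.int(1L, D + 1L))
  w <- pmax(diff(Fv), 0)
  norm <- Fv[D + 1L] - Fv[1L]
  if (!is.finite(norm) || norm <= 0)
    stop("degenerate duration model: no probability mass on 1..D_max")
  pmf <- w / norm
  survivor <- pmax((Fv[D + 1L] - Fv[seq_len(D)]) / norm, 0)
  list(pmf = pmf, survivor = survivor)
}
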