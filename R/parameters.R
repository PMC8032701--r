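#' Emission coefficients of the zero-inflated Poisson observation model
#'
#' State-specific log-linear intensity coefficients and the logistic
#' zero-inflation coefficients. Zero inflation is confined to state 1 (the
#' resting state); states 2..M emit plain Poisson counts. For identifiability
#' and interpretability the state intercepts `b0` must be strictly increasing
#' and every column of `b1` and `gamma` nondecreasing in the state index, so
#' that the intensity lambda(m, z, x) is strictly increasing in m for all
#' binary covariate patterns.
#'
#' @param b00 Zero-inflation intercept (scalar).
#' @param b10 Zero-inflation treatment coefficients (length q).
#' @param gamma0 Zero-inflation environment coefficients (length p).
#' @param b0 State intensity intercepts (length M, strictly increasing).
#' @param b1 State treatment coefficients (M x q matrix, columns
#'   nondecreasing).
#' @param gamma State environment coefficients (M x p matrix, columns
#'   nondecreasing).
#' @return An object of class `"emission_coefficients"`.
#' @export
emission_coefficients <- function(b00, b10, gamma0, b0, b1, gamma) {
  M <- length(b0)
  b1 <- as.matrix(b1); gamma <- as.matrix(gamma)
  if (length(b10) == 0L) b10 <- numeric(0)
  if (length(gamma0) == 0L) gamma0 <- numeric(0)
  if (nrow(b1) != M && ncol(b1) == 0L) b1 <- matrix(0, M, 0)
  if (nrow(gamma) != M && ncol(gamma) == 0L) gamma <- matrix(0, M, 0)
  structure(list(b00 = as.numeric(b00), b10 = as.numeric(b10),
                 gamma0 = as.numeric(gamma0), b0 = as.numeric(b0),
                 b1 = b1, gamma = gamma),
            class = "emission_coefficients")
}

#' Dwell-duration model coefficients
#'
#' Each state's dwell time follows a discretized accelerated failure time
#' model: a base density (Weibull or gamma, with state-specific `shape` and
#' `scale`) whose time axis is rescaled by the acceleration factor
#' `exp(c'x + eta'z)`. The AFT regression carries no intercept; it is
#' absorbed by the free `scale` parameter.
#'
#' @param shape Positive base-density shapes (length M).
#' @param scale Positive base-density scales (length M).
#' @param c Treatment coefficients on log acceleration (M x q matrix).
#' @param eta Environment coefficients on log acceleration (M x p matrix).
#' @return An object of class `"duration_model"`.
#' @export
duration_model <- function(shape, scale, c, eta) {
  M <- length(shape)
  c <- as.matrix(c); eta <- as.matrix(eta)
  if (nrow(c) != M && ncol(c) == 0L) c <- matrix(0, M, 0)
  if (nrow(eta) != M && ncol(eta) == 0L) eta <- matrix(0, M, 0)
  structure(list(shape = as.numeric(shape), scale = as.numeric(scale),
                 c = c, eta = eta),
            class = "duration_model")
}

#' Transition coefficients of the multinomial-logit jump model
#'
#' Conditional on leaving state m, the destination l != m follows a
#' multinomial logistic model with logits `d_coef[m, l, ]'x + rho[m, l, ]'z`.
#' Self-transitions are structurally excluded (the dwell model owns state
#' persistence) and the lowest-index allowed destination of each origin is
#' the softmax reference category with coefficients fixed at zero.
#'
#' @param d_coef Treatment coefficient array, dim `c(M, M, q)`.
#' @param rho Environment coefficient array, dim `c(M, M, p)`.
#' @return An object of class `"transition_coefficients"`.
#' @export
transition_coefficients <- function(d_coef, rho) {
  structure(list(d_coef = d_coef, rho = rho),
            class = "transition_coefficients")
}

#' Full subject-specific parameter set
#'
#' Collects everything the model needs for one subject: the initial state
#' distribution, emission, duration, and transition coefficients.
#'
#' @param delta Initial state probabilities (length M, simplex).
#' @param emission An [emission_coefficients()] object.
#' @param duration A [duration_model()] object.
#' @param transition A [transition_coefficients()] object.
#' @return An object of class `"subject_parameters"`.
#' @export
subject_parameters <- function(delta, emission, duration, transition) {
  structure(list(delta = as.numeric(delta), emission = emission,
                 duration = duration, transition = transition),
            class = "subject_parameters")
}

#' Default (all-zero unconstrained) parameter set
#'
#' The image of the zero vector under [from_unconstrained()]: uniform initial
#' distribution, unit emission intercept spacing, unit shapes/scales, zero
#' covariate effects. Always passes [validate_parameters()].
#'
#' @param config An [model_config()] object.
#' @return A valid `"subject_parameters"` object.
#' @export
default_parameters <- function(config) {
  from_unconstrained(rep(0, param_layout(config)$length), config)
}

#' Validate a subject parameter set against the model invariants
#'
#' Checks dimensions, the simplex constraint on the initial distribution, the
#' strict ordering of emission intercepts, the nondecreasing ordering of the
#' emission slope columns, positivity of duration shapes/scales, and the
#' structural zeros of the transition model. Validation never raises; it
#' returns a data frame of violations (zero rows when the parameters are
#' valid), each with a machine-readable code.
#'
#' @param params A `"subject_parameters"` object.
#' @param config An [model_config()] object.
#' @return A data frame with columns `code` and `message`; zero rows iff
#'   the parameters satisfy every invariant.
#' @export
#' @examples
#' cfg <- model_config(M = 2, q = 0, p = 0)
#' validate_parameters(default_parameters(cfg), cfg)
validate_parameters <- function(params, config) {
  viol <- list()
  add <- function(code, message)
    viol[[length(viol) + 1L]] <<- data.frame(code = code, message = message,
                                             stringsAsFactors = FALSE)
  M <- config$M; q <- config$q; p <- config$p
  em <- params$emission; du <- params$duration; tr <- params$transition

  if (length(params$delta) != M)
    add("delta_dim", sprintf("delta has length %d, expected M = %d",
                             length(params$delta), M))
  else {
    if (any(!is.finite(params$delta)) || any(params$delta < -1e-12))
      add("delta_nonneg", "delta entries must be finite and >= 0")
    if (abs(sum(params$delta) - 1) > 1e-8)
      add("delta_simplex", sprintf("delta sums to %.10f, expected 1",
                                   sum(params$delta)))
  }

  if (length(em$b00) != 1L) add("b00_dim", "b00 must be a scalar")
  if (length(em$b10) != q) add("b10_dim", "b10 length must equal q")
  if (length(em$gamma0) != p) add("gamma0_dim", "gamma0 length must equal p")
  if (length(em$b0) != M)
    add("b0_dim", "b0 length must equal M")
  else if (M > 1L && any(diff(em$b0) <= 0))
    add("b0_order", "emission intercepts b0 must be strictly increasing in m")
  if (!all(dim(em$b1) == c(M, q)))
    add("b1_dim", "b1 must be an M x q matrix")
  else if (M > 1L && q > 0L && any(apply(em$b1, 2, function(col) any(diff(col) < -1e-12))))
    add("b1_order", "each column of b1 must be nondecreasing in m")
  if (!all(dim(em$gamma) == c(M, p)))
    add("gamma_dim", "gamma must be an M x p matrix")
  else if (M > 1L && p > 0L && any(apply(em$gamma, 2, function(col) any(diff(col) < -1e-12))))
    add("gamma_order", "each column of gamma must be nondecreasing in m")

  if (length(du$shape) != M || length(du$scale) != M)
    add("duration_dim", "duration shape/scale must have length M")
  else {
    if (any(!is.finite(du$shape)) || any(du$shape <= 0))
      add("shape_pos", "duration shapes must be strictly positive")
    if (any(!is.finite(du$scale)) || any(du$scale <= 0))
      add("scale_pos", "duration scales must be strictly positive")
  }
  if (!all(dim(du$c) == c(M, q))) add("c_dim", "duration c must be M x q")
  if (!all(dim(du$eta) == c(M, p))) add("eta_dim", "duration eta must be M x p")

  if (M >= 2L) {
    ok_d <- all(dim(tr$d_coef) == c(M, M, q)) || (q == 0L && length(tr$d_coef) == 0L)
    ok_r <- all(dim(tr$rho) == c(M, M, p)) || (p == 0L && length(tr$rho) == 0L)
    if (!ok_d) add("trans_d_dim", "transition d_coef must have dim c(M, M, q)")
    if (!ok_r) add("trans_rho_dim", "transition rho must have dim c(M, M, p)")
    if (ok_d && ok_r && (q > 0L || p > 0L)) {
      for (m in seq_len(M)) {
        ref <- transition_reference(m)
        bad <- FALSE
        if (q > 0L && any(abs(tr$d_coef[m, ref, ]) > 1e-12)) bad <- TRUE
        if (p > 0L && any(abs(tr$rho[m, ref, ]) > 1e-12)) bad <- TRUE
        if (bad)
          add("trans_reference",
              sprintf("origin %d: reference destination %d coefficients must be zero", m, ref))
      }
    }
  }

  if (length(viol) == 0L)
    data.frame(code = character(0), message = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, viol)
}

stop_if_invalid <- function(params, config) {
  v <- validate_parameters(params, config)
  if (nrow(v) > 0L)
    stop("invalid subject parameters: ",
         paste(sprintf("[%s] %s", v$code, v$message), collapse = "; "))
  invisible(TRUE)
}

#' Map a subject parameter set to the unconstrained real vector
#'
#' The constrained parameter space (simplex initial distribution, strictly
#' increasing emission intercepts, nondecreasing slope columns, positive
#' shapes/scales) is reparameterized so that any real vector corresponds to a
#' valid parameter set: centered log-ratios for the simplex, a first value
#' plus exponential-map increments for strictly increasing sequences, squared
#' increments for nondecreasing sequences (equality representable), and log
#' maps for positive scalars. `from_unconstrained()` is the total inverse.
#'
#' @param params A valid `"subject_parameters"` object.
#' @param config An [model_config()] object.
#' @return Numeric vector of length `param_layout(config)$length`.
#' @seealso [from_unconstrained()]
#' @export
to_unconstrained <- function(params, config) {
  lay <- param_layout(config)
  M <- config$M; q <- config$q; p <- config$p
  u <- numeric(lay$length)
  em <- params$emission; du <- params$duration; tr <- params$transition

  if (M > 1L)
    u[lay$idx$delta] <- log(params$delta[-M]) - log(params$delta[M])
  u[lay$idx$b00] <- em$b00
  u[lay$idx$b10] <- em$b10
  u[lay$idx$gamma0] <- em$gamma0
  u[lay$idx$b0] <- c(em$b0[1L],
                     if (M > 1L) log(diff(em$b0)) else numeric(0))
  enc_nondec <- function(col) c(col[1L],
                                if (M > 1L) sqrt(pmax(diff(col), 0)) else numeric(0))
  if (q > 0L) u[lay$idx$b1] <- as.numeric(apply(em$b1, 2, enc_nondec))
  if (p > 0L) u[lay$idx$gamma] <- as.numeric(apply(em$gamma, 2, enc_nondec))
  u[lay$idx$log_shape] <- log(du$shape)
  u[lay$idx$log_scale] <- log(du$scale)
  if (q > 0L) u[lay$idx$c] <- as.numeric(du$c)
  if (p > 0L) u[lay$idx$eta] <- as.numeric(du$eta)
  if (M >= 3L && (q + p) > 0L) {
    vals <- numeric(0)
    for (m in seq_len(M)) {
      dests <- setdiff(seq_len(M), m)
      dests <- dests[dests != transition_reference(m)]
      for (l in dests) {
        if (q > 0L) vals <- c(vals, tr$d_coef[m, l, ])
        if (p > 0L) vals <- c(vals, tr$rho[m, l, ])
      }
    }
    u[lay$idx$trans] <- vals
  }
  u
}

#' @rdname to_unconstrained
#' @param u Numeric vector of length `param_layout(config)$length`.
#' @return For `from_unconstrained()`: a valid `"subject_parameters"` object.
#' @export
from_unconstrained <- function(u, config) {
  lay <- param_layout(config)
  if (length(u) != lay$length)
    stop(sprintf("unconstrained vector has length %d, expected %d",
                 length(u), lay$length))
  M <- config$M; q <- config$q; p <- config$p

  delta <- if (M > 1L) {
    g <- c(u[lay$idx$delta], 0)
    e <- exp(g - max(g)); e / sum(e)
  } else 1
  b00 <- u[lay$idx$b00]
  b10 <- u[lay$idx$b10]
  gamma0 <- u[lay$idx$gamma0]
  vb0 <- u[lay$idx$b0]
  b0 <- cumsum(c(vb0[1L], if (M > 1L) exp(vb0[-1L]) else numeric(0)))
  dec_nondec <- function(v) cumsum(c(v[1L], if (M > 1L) v[-1L]^2 else numeric(0)))
  b1 <- matrix(0, M, q)
  if (q > 0L) {
    vm <- matrix(u[lay$idx$b1], nrow = M)
    for (j in seq_len(q)) b1[, j] <- dec_nondec(vm[, j])
  }
  gam <- matrix(0, M, p)
  if (p > 0L) {
    vm <- matrix(u[lay$idx$gamma], nrow = M)
    for (j in seq_len(p)) gam[, j] <- dec_nondec(vm[, j])
  }
  shape <- exp(u[lay$idx$log_shape])
  scale <- exp(u[lay$idx$log_scale])
  cmat <- matrix(if (q > 0L) u[lay$idx$c] else numeric(0), M, q)
  eta <- matrix(if (p > 0L) u[lay$idx$eta] else numeric(0), M, p)
  d_coef <- array(0, c(M, M, q))
  rho <- array(0, c(M, M, p))
  if (M >= 3L && (q + p) > 0L) {
    v <- u[lay$idx$trans]; k <- 0L
    for (m in seq_len(M)) {
      dests <- setdiff(seq_len(M), m)
      dests <- dests[dests != transition_reference(m)]
      for (l in dests) {
        if (q > 0L) { d_coef[m, l, ] <- v[k + seq_len(q)]; k <- k + q }
        if (p > 0L) { rho[m, l, ] <- v[k + seq_len(p)]; k <- k + p }
      }
    }
  }
  subject_parameters(
    delta = delta,
    emission = emission_coefficients(b00, b10, gamma0, b0, b1, gam),
    duration = duration_model(shape, scale, cmat, eta),
    transition = transition_coefficients(d_coef, rho))
}
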