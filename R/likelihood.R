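# Builds the per-pattern inputs of the log-space recursions from the R-level
# component distributions. The C++ objective used by the fitter reimplements
# this for speed; tests assert the two paths agree.
build_hsmm_inputs <- function(series, params, config) {
  M <- config$M; D <- config$D_max
  pat <- covariate_patterns(series)
  K <- pat$K

  logf <- matrix(0, series$T, M)
  for (m in seq_len(M)) {
    p0 <- numeric(K); lam <- numeric(K)
    for (k in seq_len(K)) {
      ep <- emission_params(m, pat$X[k, ], pat$Z[k, ], params$emission)
      p0[k] <- ep$p_zero; lam[k] <- ep$lam
    }
    logf[, m] <- zip_log_pmf(series$y, p0[pat$index], lam[pat$index])
  }
  # floor at a finite sentinel so the recursion's cumulative emission sums
  # stay well-defined even where a per-minute probability underflows
  logf[logf < -1e8] <- -1e8

  logr <- array(-Inf, c(K, M, D))
  logS <- array(-Inf, c(K, M, D))
  if (M > 1L) {
    for (k in seq_len(K)) {
      for (m in seq_len(M)) {
        dp <- duration_pmf(m, pat$X[k, ], pat$Z[k, ], params$duration, config)
        logr[k, m, ] <- log(dp$pmf)
        logS[k, m, ] <- log(dp$survivor)
      }
    }
  }

  logQ <- array(-Inf, c(K, M, M))
  if (M > 1L) {
    for (k in seq_len(K)) {
      for (m in seq_len(M)) {
        row <- transition_row(m, pat$X[k, ], pat$Z[k, ], params$transition)
        logQ[k, m, ] <- log(row)
      }
    }
  }

  list(logf = logf, logr = logr, logS = logS, logQ = logQ,
       pattern0 = pat$index - 1L, K = K,
       logdelta = log(params$delta))
}

#' Exact forward log-likelihood of one subject's series
#'
#' Evaluates `log P(Y^{1:T} | X^{1:T}, Z^{1:T}; theta)` under the
#' explicit-duration generative model: initial state from `delta`, dwell
#' lengths from the discretized AFT distribution (covariates taken at the
#' minute a dwell begins), jumps from the multinomial-logit transition model
#' (covariates at the minute the transition occurs), and counts conditionally
#' independent given the current state and covariates. The final dwell is
#' right-censored through the dwell survivor function. The recursion runs in
#' log space with cost `O(T * M * (M + D_max))`.
#'
#' @param series An [activity_series()] object.
#' @param params A valid `"subject_parameters"` object.
#' @param config An [model_config()] object.
#' @return Scalar log-likelihood (<= 0).
#' @export
forward_log_likelihood <- function(series, params, config) {
  check_series_config(series, config)
  stop_if_invalid(params, config)
  if (series$T < 1L) stop("empty series")
  inp <- build_hsmm_inputs(series, params, config)
  cpp_forward(inp$logf, as.numeric(inp$logr), as.numeric(inp$logS),
              as.numeric(inp$logQ), inp$pattern0, inp$logdelta,
              inp$K, config$D_max)
}

#' Brute-force likelihood by exhaustive dwell enumeration (test oracle)
#'
#' Enumerates every segmentation of `1..T` into dwells with states (no two
#' adjacent dwells in the same state; the final dwell right-censored) and
#' sums the exact path probabilities. Exponential cost; refuses `T > 12`.
#' This is the reference implementation the forward recursion is verified
#' against; it shares only the component-distribution functions, not the
#' recursion.
#'
#' @inheritParams forward_log_likelihood
#' @return Scalar log-likelihood.
#' @export
brute_force_log_likelihood <- function(series, params, config) {
  check_series_config(series, config)
  stop_if_invalid(params, config)
  if (series$T > 12L) stop("brute-force enumeration refuses T > 12")
  enum <- enumerate_paths(series, params, config)
  mx <- max(enum$logp)
  mx + log(sum(exp(enum$logp - mx)))
}

# Enumerates all dwell segmentations, returning per-path log-probabilities
# and per-path minute-level state sequences (used by both the brute-force
# likelihood and the exhaustive Viterbi oracle in tests).
enumerate_paths <- function(series, params, config) {
  M <- config$M; D <- config$D_max; Tn <- series$T
  if (M == 1L) {
    lp <- sum(zip_log_pmf(series$y,
                          vapply(seq_len(Tn), function(t)
                            emission_params(1L, series$x[t, ], series$z[t, ],
                                            params$emission)$p_zero, 0),
                          vapply(seq_len(Tn), function(t)
                            emission_params(1L, series$x[t, ], series$z[t, ],
                                            params$emission)$lam, 0)))
    return(list(logp = lp, states = matrix(1L, 1, Tn)))
  }
  # per-minute per-state emission log-probs
  logf <- matrix(0, Tn, M)
  for (t in seq_len(Tn)) {
    for (m in seq_len(M)) {
      ep <- emission_params(m, series$x[t, ], series$z[t, ], params$emission)
      logf[t, m] <- zip_log_pmf(series$y[t], ep$p_zero, ep$lam)
    }
  }
  dur_at <- function(m, s) duration_pmf(m, series$x[s, ], series$z[s, ],
                                        params$duration, config)
  logps <- numeric(0)
  paths <- list()
  recurse <- function(s, prev, acc, states) {
    for (m in seq_len(M)) {
      if (!is.na(prev) && m == prev) next
      jump <- if (is.na(prev)) log(params$delta[m])
              else log(transition_row(prev, series$x[s, ], series$z[s, ],
                                      params$transition)[m])
      if (jump == -Inf) next
      dp <- dur_at(m, s)
      for (d in seq_len(min(D, Tn - s + 1L))) {
        emis <- sum(logf[s:(s + d - 1L), m])
        st2 <- states; st2[s:(s + d - 1L)] <- m
        if (s + d - 1L == Tn) {
          lp <- acc + jump + log(dp$survivor[d]) + emis
          if (lp > -Inf) {
            logps[[length(logps) + 1L]] <<- lp
            paths[[length(paths) + 1L]] <<- st2
          }
        } else {
          lr <- log(dp$pmf[d])
          if (lr > -Inf)
            recurse(s + d, m, acc + jump + lr + emis, st2)
        }
      }
    }
  }
  recurse(1L, NA, 0, integer(Tn))
  list(logp = unlist(logps), states = do.call(rbind, paths))
}
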