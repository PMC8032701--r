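#' Optimizer settings for subject-level maximum likelihood
#'
#' @param n_restarts Number of seeded optimizer starts (default 5). The first
#'   start is a deterministic moment-based initialization; subsequent starts
#'   perturb it with Gaussian noise of sd `restart_sd` on the unconstrained
#'   scale.
#' @param reltol Relative convergence tolerance of the quasi-Newton
#'   optimizer (default 1e-6).
#' @param maxit Maximum optimizer iterations per start (default 2000).
#' @param restart_sd Perturbation sd for restarts (default 0.5).
#' @param init Optional explicit unconstrained start vector (full layout
#'   length); replaces the moment-based initialization of the first start.
#' @param min_T_factor The fit refuses series shorter than
#'   `min_T_factor * (number of free parameters)` minutes (default 50);
#'   set to 0 to disable.
#' @param compute_gradient Whether to report the central-difference gradient
#'   norm at the optimum (default TRUE).
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(n_restarts = 5L, reltol = 1e-6, maxit = 2000L,
                        restart_sd = 0.5, init = NULL, min_T_factor = 50,
                        compute_gradient = TRUE) {
  structure(list(n_restarts = as.integer(n_restarts), reltol = reltol,
                 maxit = as.integer(maxit), restart_sd = restart_sd,
                 init = init, min_T_factor = min_T_factor,
                 compute_gradient = compute_gradient),
            class = "fit_control")
}

# Indices of the unconstrained coordinates actually optimized. The initial
# distribution delta is held fixed (uniform) during optimization: for a
# single sequence it is not meaningfully estimable and the recursion is
# insensitive to it beyond the first dwell; an optional post-fit
# re-estimation from the decoded path is available (see fit_subject). For
# M = 1 the dwell and transition machinery drops out of the likelihood, so
# those blocks are excluded too (they would be flat directions).
free_parameter_indices <- function(config) {
  lay <- param_layout(config)
  blocks <- if (config$M == 1L) c("b00", "b10", "gamma0", "b0", "b1", "gamma")
            else c("b00", "b10", "gamma0", "b0", "b1", "gamma",
                   "log_shape", "log_scale", "c", "eta", "trans")
  sort(unlist(lay$idx[blocks], use.names = FALSE))
}

# Moment-based deterministic initialization on the unconstrained scale:
# zero-inflation intercept from the observed zero fraction, state intensity
# intercepts from quantiles of the positive counts, everything else neutral.
init_unconstrained <- function(series, config) {
  lay <- param_layout(config)
  u <- numeric(lay$length)
  M <- config$M
  zf <- min(max(mean(series$y == 0), 0.05), 0.95)
  u[lay$idx$b00] <- qlogis(zf)
  pos <- series$y[series$y > 0]
  lams <- if (length(pos) >= M)
    as.numeric(quantile(pos, (seq_len(M) - 0.5) / M, type = 1))
  else seq_len(M)
  lams[1L] <- lams[1L] / 2          # resting-state intensity below the bulk
  lams <- pmax(lams, 0.05)
  lams <- cummax(lams) * (1 + 0.05 * (seq_len(M) - 1))  # force strict order
  b0t <- log(lams)                  # targets on the log-intensity scale
  u[lay$idx$b0] <- c(b0t[1L],
                     if (M > 1L) log(pmax(diff(b0t), 1e-2)) else numeric(0))
  u[lay$idx$log_scale] <- log(3)    # ~3-minute prior dwell scale
  # squared-increment coordinates of the nondecreasing slope columns start
  # slightly off zero: at exactly zero their gradient vanishes identically
  # and the states' slopes could never separate
  if (M > 1L) {
    inc <- rep(c(FALSE, rep(TRUE, M - 1L)), length.out = M)
    if (config$q > 0L)
      u[lay$idx$b1][rep(inc, config$q)] <- 0.1
    if (config$p > 0L)
      u[lay$idx$gamma][rep(inc, config$p)] <- 0.1
  }
  u
}

#' Subject-level maximum-likelihood fit
#'
#' Maximizes the exact forward log-likelihood over the unconstrained
#' reparameterization with BFGS, using multiple seeded restarts, and returns
#' the best start. Deterministic given `(series, seed, control)`.
#'
#' @param series An [activity_series()] object.
#' @param config An [model_config()] object; `M` may be overridden.
#' @param M Number of latent states (defaults to `config$M`).
#' @param seed Integer seed controlling the restart perturbations.
#' @param control A [fit_control()] list.
#' @param reestimate_delta If TRUE, after fitting, the initial distribution
#'   is re-estimated once from the sample state frequencies of the decoded
#'   Viterbi path (with a 0.5 pseudo-count); default FALSE, keeping the
#'   uniform delta the likelihood was maximized under.
#' @return An object of class `"subject_fit"` with elements `params_hat`,
#'   `loglik`, `n_params`, `bic` (`-2 loglik + n_params log T`), `converged`,
#'   `n_restarts_used`, `gradient_norm`, `M`, `config`, `subject_id`, `T`.
#' @export
fit_subject <- function(series, config, M = config$M, seed = 1L,
                        control = fit_control(), reestimate_delta = FALSE) {
  check_series_config(series, config)
  if (M != config$M) {
    config <- model_config(M = M, D_max = config$D_max,
                           duration_family = config$duration_family,
                           q = config$q, p = config$p, d = config$d)
  }
  lay <- param_layout(config)
  free <- free_parameter_indices(config)
  n_free <- length(free)
  if (control$min_T_factor > 0 && series$T < control$min_T_factor * n_free)
    stop(sprintf(
      "series too short: T = %d < %g x %d free parameters; lower min_T_factor to override",
      series$T, control$min_T_factor, n_free))
  if (sd(series$y) == 0)
    warning("degenerate data: all activity counts identical")

  pat <- covariate_patterns(series)
  fam <- match(config$duration_family, c("weibull", "gamma")) - 1L
  lgy <- lgamma(series$y + 1)
  pattern0 <- pat$index - 1L
  u_full <- numeric(lay$length)

  obj <- function(ufree) {
    u_full[free] <- ufree
    cpp_neg_loglik(u_full, series$y, lgy, pattern0, pat$X, pat$Z,
                   config$M, config$D_max, fam)
  }
  obj_grad <- function(ufree) {
    u_full[free] <- ufree
    cpp_neg_loglik_grad(u_full, series$y, lgy, pattern0, pat$X, pat$Z,
                        config$M, config$D_max, fam)$gradient[free]
  }

  u0 <- if (!is.null(control$init)) {
    if (length(control$init) != lay$length)
      stop("control$init has the wrong length")
    control$init
  } else init_unconstrained(series, config)

  set.seed(as.integer(seed))
  n_restarts <- max(1L, control$n_restarts)
  perturb <- if (n_restarts > 1L)
    matrix(rnorm((n_restarts - 1L) * n_free, sd = control$restart_sd),
           nrow = n_free)
  else NULL

  best <- NULL
  for (j in seq_len(n_restarts)) {
    start <- u0[free]
    if (j > 1L) start <- start + perturb[, j - 1L]
    res <- tryCatch(
      optim(start, obj, gr = obj_grad, method = "BFGS",
            control = list(maxit = control$maxit, reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("all optimizer restarts failed")

  converged <- best$convergence == 0L && best$value < 1e9
  u_hat <- u_full
  u_hat[free] <- best$par
  params_hat <- from_unconstrained(u_hat, config)
  loglik <- -best$value

  grad_norm <- NA_real_
  if (isTRUE(control$compute_gradient))
    grad_norm <- sqrt(sum(obj_grad(best$par)^2))

  if (isTRUE(reestimate_delta) && config$M > 1L) {
    dec <- viterbi_decode(series, params_hat, config)
    freq <- tabulate(dec$states, nbins = config$M) + 0.5
    params_hat$delta <- freq / sum(freq)
  }

  structure(list(subject_id = series$subject_id,
                 params_hat = params_hat,
                 loglik = loglik,
                 n_params = n_free,
                 bic = -2 * loglik + n_free * log(series$T),
                 converged = converged,
                 n_restarts_used = n_restarts,
                 gradient_norm = grad_norm,
                 M = config$M, T = series$T,
                 config = config),
            class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf(
    "subject_fit: subject %s, M = %d, T = %d\n  loglik = %.3f, n_params = %d, BIC = %.2f, converged = %s\n",
    x$subject_id, x$M, x$T, x$loglik, x$n_params, x$bic, x$converged))
  invisible(x)
}

#' Select the number of latent states by BIC
#'
#' Fits every candidate number of states and returns the BIC minimizer,
#' with ties broken toward the smaller model. Per-candidate failures are
#' recorded in the table without aborting the sweep.
#'
#' @param series An [activity_series()] object.
#' @param M_candidates Integer vector of candidate state counts.
#' @param config An [model_config()] template (its `M` is ignored).
#' @param seed Seed forwarded to each candidate fit.
#' @param control A [fit_control()] list.
#' @return List with `M_star` and `table` (data frame: `M`, `loglik`,
#'   `n_params`, `bic`, `converged`, `error`), plus `fits` (the per-candidate
#'   `subject_fit` objects, NULL where a fit failed).
#' @export
select_num_states <- function(series, M_candidates, config, seed = 1L,
                              control = fit_control()) {
  if (length(M_candidates) < 1L) stop("no candidate state counts supplied")
  M_candidates <- sort(unique(as.integer(M_candidates)))
  rows <- list(); fits <- list()
  for (M in M_candidates) {
    fit <- tryCatch(fit_subject(series, config, M = M, seed = seed,
                                control = control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        M = M, loglik = NA_real_, n_params = NA_integer_, bic = NA_real_,
        converged = FALSE, error = conditionMessage(fit))
      fits[as.character(M)] <- list(NULL)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        M = M, loglik = fit$loglik, n_params = fit$n_params, bic = fit$bic,
        converged = fit$converged, error = NA_character_)
      fits[[as.character(M)]] <- fit
    }
  }
  table <- do.call(rbind, rows)
  ok <- which(!is.na(table$bic))
  if (length(ok) == 0L) stop("every candidate fit failed")
  M_star <- table$M[ok[which.min(table$bic[ok])]]
  list(M_star = M_star, table = table, fits = fits)
}
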