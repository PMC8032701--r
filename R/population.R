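#' Stack subject-level coefficient estimates for the second stage
#'
#' Collects one family of subject-specific maximum-likelihood coefficient
#' estimates into an `n x J` matrix (one row per converged subject), aligned
#' across subjects by the monotone-intensity state ordering. Unconverged
#' subjects are excluded and reported via the `"excluded"` attribute.
#'
#' @param fits List of [fit_subject()] results sharing `M` and covariate
#'   dimensions.
#' @param family Which coefficient family: `"emission"` (treatment effects
#'   on log state intensity, `b1`, states 1..M), `"zero"` (treatment effect
#'   on the log-odds of structural zero, `b10`), `"duration"` (treatment
#'   effects on log dwell acceleration, `c`), or `"transition"` (non-reference
#'   destination logit effects, `d`).
#' @return Matrix with one row per included subject (rownames = subject ids)
#'   and attribute `excluded` listing dropped subject ids.
#' @export
stack_subject_estimates <- function(fits, family = c("emission", "zero",
                                                     "duration", "transition")) {
  family <- match.arg(family)
  if (length(fits) == 0L) stop("no subject fits supplied")
  Ms <- vapply(fits, function(f) as.integer(f$M), 0L)
  if (length(unique(Ms)) != 1L)
    stop("inconsistent number of states across subject fits")
  M <- Ms[[1L]]
  q <- fits[[1L]]$config$q
  keep <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  excluded <- vapply(fits[!keep], function(f) f$subject_id, "")
  fits <- fits[keep]
  if (length(fits) == 0L) stop("no converged subject fits")

  extract <- function(f) {
    pm <- f$params_hat
    switch(family,
      emission = {
        v <- as.numeric(pm$emission$b1)
        names(v) <- paste0("state", rep(seq_len(M), q),
                           if (q > 1L) paste0(".x", rep(seq_len(q), each = M)) else "")
        v
      },
      zero = {
        v <- pm$emission$b10
        names(v) <- if (q > 1L) paste0("zero.x", seq_len(q)) else "zero"
        v
      },
      duration = {
        v <- as.numeric(pm$duration$c)
        names(v) <- paste0("state", rep(seq_len(M), q),
                           if (q > 1L) paste0(".x", rep(seq_len(q), each = M)) else "")
        v
      },
      transition = {
        vals <- c(); nms <- c()
        for (m in seq_len(M)) {
          dests <- setdiff(seq_len(M), m)
          dests <- dests[dests != transition_reference(m)]
          for (l in dests) for (j in seq_len(q)) {
            vals <- c(vals, pm$transition$d_coef[m, l, j])
            nms <- c(nms, paste0("from", m, ".to", l,
                                 if (q > 1L) paste0(".x", j) else ""))
          }
        }
        if (length(vals) == 0L)
          stop("no free transition coefficients for M = ", M)
        names(vals) <- nms
        vals
      })
  }
  proto <- extract(fits[[1L]])
  est <- vapply(fits, extract, proto)
  est <- if (length(proto) == 1L)
    matrix(est, ncol = 1, dimnames = list(NULL, names(proto)))
  else t(est)
  rownames(est) <- vapply(fits, function(f) f$subject_id, "")
  attr(est, "excluded") <- unname(excluded)
  est
}

#' Second-stage least-squares population regression with sandwich covariance
#'
#' Regresses subject-level coefficient estimates on baseline covariates by
#' ordinary least squares, component by component (the stacked design is
#' block diagonal, `I (x) [1, W]`, so the joint regression decomposes).
#' Standard errors use the heteroskedasticity-robust sandwich
#' `(X'X)^{-1} X' diag(e^2) X (X'X)^{-1}` with the raw squared residuals
#' (HC0), matching the asymptotic covariance of the two-stage estimator.
#' Baseline covariates are centered by default so each intercept estimates
#' the average effect over the sample.
#'
#' @param estimates `n x J` matrix from [stack_subject_estimates()].
#' @param baseline `n x d` numeric matrix/data frame of baseline covariates
#'   W (rows aligned with `estimates`), or `NULL` for an intercept-only
#'   regression.
#' @param center Center the baseline covariates (default TRUE).
#' @return An object of class `"population_estimates"`: `coefficients`
#'   (`(d+1) x J`), `se`, `vcov` (array `(d+1) x (d+1) x J`), `n`,
#'   `responses`, `center`, `center_values`.
#' @export
population_regress <- function(estimates, baseline = NULL, center = TRUE) {
  estimates <- as.matrix(estimates)
  n <- nrow(estimates)
  if (n < 1L) stop("empty estimate matrix")
  if (is.null(baseline)) {
    W <- matrix(0, n, 0)
  } else {
    W <- as.matrix(as.data.frame(baseline))
    if (!is.numeric(W)) stop("baseline covariates must be numeric")
    if (nrow(W) != n)
      stop("baseline table rows must align with the estimate matrix")
  }
  d <- ncol(W)
  if (n < d + 2L)
    stop(sprintf("need at least d + 2 = %d subjects, have %d", d + 2L, n))
  center_values <- if (center && d > 0L) colMeans(W) else rep(0, d)
  Wc <- sweep(W, 2L, center_values)
  X <- cbind(`(Intercept)` = 1, Wc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient second-stage design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  XtX_inv <- chol2inv(qr.R(qrX))
  J <- ncol(estimates)
  coefs <- matrix(NA_real_, ncol(X), J,
                  dimnames = list(colnames(X), colnames(estimates)))
  ses <- coefs
  vc <- array(NA_real_, c(ncol(X), ncol(X), J),
              dimnames = list(colnames(X), colnames(X), colnames(estimates)))
  for (j in seq_len(J)) {
    yj <- estimates[, j]
    beta <- qr.coef(qrX, yj)
    e <- yj - as.numeric(X %*% beta)
    meat <- crossprod(X * e)            # X' diag(e^2) X
    V <- XtX_inv %*% meat %*% XtX_inv
    V <- (V + t(V)) / 2
    coefs[, j] <- beta
    vc[, , j] <- V
    ses[, j] <- sqrt(pmax(diag(V), 0))
  }
  structure(list(coefficients = coefs, se = ses, vcov = vc, n = n,
                 responses = colnames(estimates), center = center,
                 center_values = center_values),
            class = "population_estimates")
}

#' @export
print.population_estimates <- function(x, ...) {
  cat(sprintf("population_estimates: n = %d subjects, %d response components\n",
              x$n, length(x$responses)))
  tab <- data.frame(estimate = x$coefficients[1, ], se = x$se[1, ])
  print(round(tab, 4))
  invisible(x)
}

#' Wald z test
#'
#' `z = estimate / se`, two-sided p-value from the standard normal
#' reference distribution. Vectorized.
#'
#' @param estimate Coefficient estimate(s).
#' @param se Positive standard error(s).
#' @return List with `z` and `p`.
#' @export
#' @examples
#' wald_test(0.0819, 0.0235)   # z ~ 3.49, p ~ 0.0005
wald_test <- function(estimate, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("`se` must be strictly positive")
  z <- estimate / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Percent effect size from a log-scale treatment coefficient
#'
#' By the reporting convention used for small log-link coefficients, the
#' percent effect is `100 * coef`; the exact exponential version
#' `100 * (exp(coef) - 1)` is available behind an explicit flag and is never
#' substituted silently.
#'
#' @param coef Log-scale coefficient(s).
#' @param exponential Use `100 * (exp(coef) - 1)` instead (default FALSE).
#' @return Percent effect size(s).
#' @export
#' @examples
#' effect_size_percent(0.0914)   # 9.14
effect_size_percent <- function(coef, exponential = FALSE) {
  if (isTRUE(exponential)) 100 * (exp(coef) - 1) else 100 * coef
}

#' Population treatment-effect table
#'
#' One row per reported parameter — the state-1 odds-of-zero treatment effect
#' followed by each state's mean-activity-count treatment effect, in
#' increasing order of state intensity — with the second-stage intercept
#' estimate (average effect under centered baseline covariates), its
#' sandwich standard error, the Wald z, and the two-sided p-value.
#'
#' @param emission A `"population_estimates"` for the `"emission"` family.
#' @param zero Optional `"population_estimates"` for the `"zero"` family.
#' @return Data frame of class `"effect_table"` with columns `parameter`,
#'   `estimate`, `se`, `z`, `p`.
#' @export
effect_table <- function(emission, zero = NULL) {
  rows <- list()
  if (!is.null(zero)) {
    w <- wald_test(zero$coefficients[1L, 1L], zero$se[1L, 1L])
    rows[[1L]] <- data.frame(parameter = "State 1: odds of zero",
                             estimate = zero$coefficients[1L, 1L],
                             se = zero$se[1L, 1L], z = w$z, p = w$p)
  }
  for (j in seq_along(emission$responses)) {
    est <- emission$coefficients[1L, j]; se <- emission$se[1L, j]
    w <- wald_test(est, se)
    state <- sub("^state([0-9]+).*$", "\\1", emission$responses[j])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("State %s: mean activity count", state),
      estimate = est, se = se, z = w$z, p = w$p)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("effect_table", "data.frame")
  out
}

#' @export
print.effect_table <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$estimate <- round(y$estimate, digits); y$se <- round(y$se, digits)
  y$z <- round(y$z, 2); y$p <- signif(y$p, 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write an effect table as CSV or Markdown
#'
#' @param x An `"effect_table"`.
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return The input, invisibly.
#' @export
write_effect_table <- function(x, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(x), path, row.names = FALSE)
  } else {
    fmt <- function(v, d) formatC(v, digits = d, format = "f")
    lines <- c("| Parameter | Estimate | Standard error | p value |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %s | %s |", x$parameter,
                       fmt(x$estimate, 4), fmt(x$se, 4), fmt(x$p, 4)))
    writeLines(lines, path)
  }
  invisible(x)
}
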