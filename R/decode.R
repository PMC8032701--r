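#' Viterbi decoding of the most probable dwell/state segmentation
#'
#' Max-product analogue of the forward recursion over explicit-duration
#' segmentations, with the final dwell right-censored through the survivor
#' function. Ties are broken toward the lower state index, then the shorter
#' dwell.
#'
#' @inheritParams forward_log_likelihood
#' @return An object of class `"decoded_path"`: `states` (length-T integer
#'   vector), `segments` (data frame with `state`, `start`, `duration`,
#'   `censored`; the final dwell is flagged censored), and `logp`, the joint
#'   log-probability of the decoded segmentation and the data.
#' @export
viterbi_decode <- function(series, params, config) {
  check_series_config(series, config)
  stop_if_invalid(params, config)
  inp <- build_hsmm_inputs(series, params, config)
  vt <- cpp_viterbi(inp$logf, as.numeric(inp$logr), as.numeric(inp$logS),
                    as.numeric(inp$logQ), inp$pattern0, inp$logdelta,
                    inp$K, config$D_max)
  nseg <- length(vt$seg_state)
  segments <- data.frame(state = vt$seg_state, start = vt$seg_start,
                         duration = vt$seg_duration,
                         censored = c(rep(FALSE, nseg - 1L), TRUE))
  structure(list(subject_id = series$subject_id, states = vt$states,
                 segments = segments, logp = vt$logp),
            class = "decoded_path")
}

#' @export
print.decoded_path <- function(x, ...) {
  cat(sprintf("decoded_path: subject %s, T = %d, %d segments, logp = %.3f\n",
              x$subject_id, length(x$states), nrow(x$segments), x$logp))
  invisible(x)
}

#' Mean percent time per decoded state, by condition
#'
#' For each condition (e.g. treatment vs placebo minutes) and each state,
#' the mean over subjects of `100 * minutes in state / minutes in condition`.
#' Each condition column sums to 100 up to rounding.
#'
#' @param paths A list of [viterbi_decode()] results (or bare integer state
#'   vectors), one per subject.
#' @param condition_labels A list (aligned with `paths`) of per-minute
#'   condition labels, each the same length as the subject's state vector.
#' @return A data frame with one row per state and one column per condition,
#'   entries in percent.
#' @export
state_occupancy <- function(paths, condition_labels) {
  if (length(paths) != length(condition_labels))
    stop("`paths` and `condition_labels` must have the same length")
  states <- lapply(paths, function(p)
    if (inherits(p, "decoded_path")) p$states else as.integer(p))
  for (i in seq_along(states))
    if (length(states[[i]]) != length(condition_labels[[i]]))
      stop(sprintf("subject %d: labels not aligned with minutes", i))
  conds <- unique(unlist(lapply(condition_labels, function(l) as.character(unique(l)))))
  all_levels <- unique(unlist(lapply(condition_labels, function(l)
    if (is.factor(l)) levels(l) else as.character(unique(l)))))
  empty <- setdiff(all_levels, conds)
  if (length(empty) > 0L)
    warning("condition(s) with no minutes excluded: ",
            paste(empty, collapse = ", "))
  M <- max(unlist(states))
  out <- matrix(NA_real_, M, length(conds),
                dimnames = list(paste0("state_", seq_len(M)), conds))
  for (cc in conds) {
    per_subj <- vapply(seq_along(states), function(i) {
      sel <- as.character(condition_labels[[i]]) == cc
      if (!any(sel)) return(rep(NA_real_, M))
      tabulate(states[[i]][sel], nbins = M) / sum(sel) * 100
    }, numeric(M))
    per_subj <- matrix(per_subj, nrow = M)
    out[, cc] <- rowMeans(per_subj, na.rm = TRUE)
  }
  data.frame(state = seq_len(M), out, check.names = FALSE, row.names = NULL)
}

#' Quantile-based model fit check
#'
#' Simulates a long trajectory from a fitted model (recycling the observed
#' covariate schedule) and pairs the marginal simulated count quantiles with
#' the empirical quantiles of the data — the numerical content of a
#' quantile-quantile fit plot. Under a sparse activity regime with more than
#' 75% zero minutes both quantile sets are zero up to the 75th percentile.
#'
#' @param fit A [fit_subject()] result (must have converged).
#' @param series The observed [activity_series()].
#' @param config The [model_config()] used for the fit.
#' @param quantile_grid Percent levels (default 1..99).
#' @param seed Integer seed for the model simulation.
#' @param length_factor Simulated length as a multiple of `T` (default 10).
#' @return Data frame with columns `percent`, `model`, `observed`.
#' @export
model_quantile_check <- function(fit, series, config,
                                 quantile_grid = 1:99, seed = 1L,
                                 length_factor = 10) {
  if (!isTRUE(fit$converged))
    stop("model_quantile_check requires a converged fit")
  n_sim <- ceiling(length_factor * series$T)
  rep_idx <- rep_len(seq_len(series$T), n_sim)
  schedule <- list(x = series$x[rep_idx, , drop = FALSE],
                   z = series$z[rep_idx, , drop = FALSE])
  sim <- simulate_subject(fit$params_hat, schedule, config, seed = seed)
  probs <- quantile_grid / 100
  data.frame(percent = quantile_grid,
             model = as.numeric(quantile(sim$series$y, probs, type = 1)),
             observed = as.numeric(quantile(series$y, probs, type = 1)))
}

#' Export decoded segments as a half-open interval table
#'
#' One row per dwell with half-open minute intervals `[start, end)`,
#' BED-style, suitable for downstream interval tools.
#'
#' @param paths List of `"decoded_path"` objects.
#' @param path Output CSV file path, or `NULL` to return the data frame.
#' @return The segment table, invisibly when written.
#' @export
export_segments <- function(paths, path = NULL) {
  tabs <- lapply(paths, function(pp) {
    data.frame(subject_id = pp$subject_id,
               start = pp$segments$start,
               end = pp$segments$start + pp$segments$duration,
               state = pp$segments$state,
               censored = pp$segments$censored)
  })
  out <- do.call(rbind, tabs)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
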