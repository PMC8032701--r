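#' One subject's per-minute activity series
#'
#' A validated container for a single subject: nonnegative integer activity
#' counts at contiguous 1-minute epochs together with the aligned per-minute
#' treatment covariates `x` and environmental covariates `z`.
#'
#' @param subject_id Opaque subject label (coerced to character).
#' @param y Nonnegative integer activity counts, one per minute.
#' @param x Treatment covariate matrix (T x q) or vector; `NULL` for q = 0.
#' @param z Environment covariate matrix (T x p) or vector; `NULL` for p = 0.
#' @param t Minute index; must be contiguous `1..T` (default).
#' @return An object of class `"activity_series"` with elements
#'   `subject_id`, `t`, `y`, `x`, `z`, and `T`.
#' @export
#' @examples
#' activity_series("cat01", y = c(0, 0, 3), x = c(0, 0, 1), z = NULL)
activity_series <- function(subject_id, y, x = NULL, z = NULL,
                            t = seq_along(y)) {
  if (length(y) < 1L) stop("activity series must contain at least one minute")
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
    stop("activity counts `y` must be nonnegative integers")
  if (!identical(as.integer(t), seq_len(length(y))))
    stop("minute index `t` must be contiguous 1..T")
  as_cov <- function(v, name) {
    if (is.null(v)) return(matrix(0, length(y), 0))
    v <- as.matrix(v)
    if (nrow(v) != length(y))
      stop(sprintf("covariate `%s` must have one row per minute", name))
    storage.mode(v) <- "double"
    v
  }
  structure(list(subject_id = as.character(subject_id),
                 t = seq_len(length(y)),
                 y = as.integer(y),
                 x = as_cov(x, "x"),
                 z = as_cov(z, "z"),
                 T = length(y)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf(
    "activity_series: subject %s, T = %d minutes, %.1f%% zeros, q = %d, p = %d\n",
    x$subject_id, x$T, 100 * mean(x$y == 0), ncol(x$x), ncol(x$z)))
  invisible(x)
}

#' Restrict a series to an analysis window
#'
#' Keeps minutes `from..to` and re-indexes them to `1..T'` (the engine
#' requires a contiguous minute index). Use one window per call: splicing
#' non-adjacent windows together would fabricate dwell continuity across
#' the cut. Typical use is restricting a crossover series to one blinded
#' treatment period.
#'
#' @param series An [activity_series()].
#' @param from,to First and last minute to keep (inclusive).
#' @return A new [activity_series()] of length `to - from + 1`.
#' @export
window_series <- function(series, from, to) {
  from <- as.integer(from); to <- as.integer(to)
  if (from < 1L || to > series$T || from > to)
    stop(sprintf("window [%d, %d] outside the series 1..%d", from, to,
                 series$T))
  idx <- from:to
  activity_series(series$subject_id, series$y[idx],
                  x = series$x[idx, , drop = FALSE],
                  z = series$z[idx, , drop = FALSE])
}

check_series_config <- function(series, config) {
  if (!inherits(series, "activity_series"))
    stop("`series` must be an activity_series object")
  if (ncol(series$x) != config$q)
    stop(sprintf("series has %d treatment covariates, config expects q = %d",
                 ncol(series$x), config$q))
  if (ncol(series$z) != config$p)
    stop(sprintf("series has %d environment covariates, config expects p = %d",
                 ncol(series$z), config$p))
  invisible(TRUE)
}

# Collapse the per-minute covariate rows to the set of unique (x, z) patterns.
# Returns the unique pattern matrices and a per-minute 1-based index. The
# engine precomputes duration/transition/emission quantities once per pattern,
# which is what makes the minute-level recursion cheap for designs whose
# covariates are categorical (binary in the motivating study).
covariate_patterns <- function(series) {
  xz <- cbind(series$x, series$z)
  if (ncol(xz) == 0L) {
    return(list(X = matrix(0, 1, 0), Z = matrix(0, 1, 0),
                index = rep(1L, series$T), K = 1L))
  }
  key <- do.call(paste, c(lapply(seq_len(ncol(xz)), function(j) xz[, j]),
                          sep = "\r"))
  uk <- !duplicated(key)
  levs <- key[uk]
  idx <- match(key, levs)
  list(X = series$x[uk, , drop = FALSE],
       Z = series$z[uk, , drop = FALSE],
       index = idx, K = length(levs))
}
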