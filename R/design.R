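#' Crossover study design
#'
#' Describes the randomized two-period crossover layout the simulator
#' emulates: an open-label baseline, a first blinded treatment period, a
#' blinded washout, and a second blinded period with treatments switched.
#' The default is the 11-week layout (2 + 3 + 3 + 3 weeks) at 1-minute
#' epochs, 1440 minutes per day.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_weeks,treatment_weeks,washout_weeks Phase lengths in
#'   weeks; the two blinded treatment periods share `treatment_weeks`.
#' @param minutes_per_day Epochs per day (default 1440 = 1-minute epochs).
#' @param night_start_min,night_end_min Minute-of-day bounds of the night
#'   window; a minute is "night" when `mod >= night_start_min` or
#'   `mod < night_end_min`. Default 18:00-06:00 (1080, 360).
#' @param phase_minutes Optional explicit override: total minutes of the
#'   four phases `c(baseline, period1, washout, period2)`; when supplied the
#'   week arguments are ignored. Used for scaled-down simulation studies.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(n_subjects = 10L, baseline_weeks = 2,
                         treatment_weeks = 3, washout_weeks = 3,
                         minutes_per_day = 1440L,
                         night_start_min = 1080L, night_end_min = 360L,
                         phase_minutes = NULL) {
  mpw <- 7 * minutes_per_day
  if (is.null(phase_minutes)) {
    phase_minutes <- c(baseline = baseline_weeks * mpw,
                       period1 = treatment_weeks * mpw,
                       washout = washout_weeks * mpw,
                       period2 = treatment_weeks * mpw)
  } else {
    if (length(phase_minutes) != 4L || any(phase_minutes < 0))
      stop("`phase_minutes` must be 4 nonnegative phase lengths")
    names(phase_minutes) <- c("baseline", "period1", "washout", "period2")
  }
  if (sum(phase_minutes) < 1) stop("design has zero total length")
  structure(list(n_subjects = as.integer(n_subjects),
                 phase_minutes = phase_minutes,
                 minutes_per_day = as.integer(minutes_per_day),
                 night_start_min = as.integer(night_start_min),
                 night_end_min = as.integer(night_end_min),
                 total_minutes = as.integer(sum(phase_minutes))),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "study_design: %d subjects, %d minutes total (%s), night window [%d, %d)\n",
    x$n_subjects, x$total_minutes,
    paste(sprintf("%s=%d", names(x$phase_minutes), x$phase_minutes),
          collapse = ", "),
    x$night_start_min, x$night_end_min))
  invisible(x)
}

#' Per-minute covariate schedule of one crossover arm
#'
#' Deterministically expands a [study_design()] into the per-minute
#' treatment indicator x and environmental indicators z for one treatment
#' sequence: sequence `"A"` receives active treatment during the first
#' blinded period, `"B"` during the second. Day 1 is a Monday; the weekend
#' indicator marks days 6 and 7 of each week.
#'
#' @param design A [study_design()].
#' @param sequence `"A"` (active first) or `"B"` (active second).
#' @param z_vars Which environmental indicators to include, a subset of
#'   `c("night", "weekend")`; use `character(0)` for p = 0.
#' @return List with `x` (T x 1 matrix), `z` (T x length(z_vars) matrix),
#'   `phase` (factor), `minute_of_day`, and `day`.
#' @export
make_crossover_schedule <- function(design, sequence = c("A", "B"),
                                    z_vars = c("night", "weekend")) {
  sequence <- match.arg(sequence)
  if (length(z_vars) > 0L)
    z_vars <- match.arg(z_vars, several.ok = TRUE)
  Tn <- design$total_minutes
  t0 <- seq_len(Tn) - 1L
  mod <- t0 %% design$minutes_per_day
  day <- t0 %/% design$minutes_per_day
  bounds <- cumsum(design$phase_minutes)
  phase_idx <- pmin(findInterval(t0, bounds) + 1L, 4L)
  phase <- factor(names(design$phase_minutes)[phase_idx],
                  levels = names(design$phase_minutes))
  active_phase <- if (sequence == "A") "period1" else "period2"
  x <- matrix(as.numeric(phase == active_phase), ncol = 1,
              dimnames = list(NULL, "treatment"))
  night <- as.numeric(mod >= design$night_start_min |
                        mod < design$night_end_min)
  weekend <- as.numeric((day %% 7) >= 5)
  zall <- cbind(night = night, weekend = weekend)
  z <- zall[, z_vars, drop = FALSE]
  list(x = x, z = z, phase = phase, minute_of_day = mod, day = day)
}
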