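#' Blank-area count
#'
#' Number of lattice cells with no space-occupying agent, excluding the
#' structural central-vein and portal-tract sites.  Blank areas arise when
#' dead cells are phagocytosed (or age out) faster than proliferation and
#' collagen deposition refill the space.
#'
#' @param state A `lobule_state`, or a bare occupancy matrix.
#' @return Integer count.
#' @export
blank_area <- function(state) {
  occ <- if (is.list(state)) state$occ else state
  sum(occ == OCC_BLANK)
}

#' Onset step of a time series
#'
#' First step at which the series strictly exceeds `fraction` of its final
#' value.  Used to date the start of collagen accumulation in a time course.
#'
#' @param series Non-negative numeric vector, one entry per step starting at
#'   step 0.
#' @param fraction Fraction of the final value to exceed (default 0.05).
#' @return Step index (0-based, matching the `step` column of a time course),
#'   or `NA` if the final value is 0 or the threshold is never exceeded.
#' @examples
#' onset_step(c(0, 0, 1, 50, 100))      # 2
#' onset_step(seq(0, 100), 0.05)        # 6
#' @export
onset_step <- function(series, fraction = 0.05) {
  final <- series[length(series)]
  if (final <= 0) return(NA_integer_)
  hit <- which(series > fraction * final)
  if (!length(hit)) return(NA_integer_)
  hit[1L] - 1L
}

#' Peak step of a time series
#'
#' Step of the series maximum; the earliest step on ties.
#'
#' @param series Non-empty numeric vector, one entry per step starting at
#'   step 0.
#' @return Step index (0-based).
#' @examples
#' peak_step(c(0, 3, 9, 9, 1))  # 2
#' @export
peak_step <- function(series) {
  which.max(series) - 1L
}

#' Dominant period of an oscillating series
#'
#' Median gap between successive local maxima that rise above a noise floor
#' (`floor_frac` of the global maximum).  Used to detect the synchronisation
#' of dead-cell peaks with the injection schedule.
#'
#' @param series Numeric vector, one entry per step.
#' @param floor_frac Noise floor as a fraction of the global maximum.
#' @return Median inter-peak gap in steps, or `NA` if fewer than two maxima
#'   clear the floor.
#' @examples
#' x <- rep(0, 50); x[seq(5, 45, by = 10)] <- 1
#' dominant_period(x)  # 10
#' @export
dominant_period <- function(series, floor_frac = 0.1) {
  n <- length(series)
  if (n < 3L) return(NA_real_)
  floor_v <- floor_frac * max(series)
  prev <- c(-Inf, series[-n])
  nxt <- c(series[-1L], -Inf)
  peaks <- which(series > floor_v & series >= prev & series >= nxt)
  # collapse plateaus to their first step
  if (length(peaks) > 1L) peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (length(peaks) < 2L) return(NA_real_)
  stats::median(diff(peaks))
}

#' Reshape a time course to tidy long format
#'
#' One row per (seed, step, variable), ready for plotting or export.
#'
#' @param tc A time-course data frame from [simulate_lobule()] or
#'   [run_ensemble()]; a `seed` column is added (as `NA`) if absent.
#' @return Long-format data frame with columns `seed`, `step`, `variable`,
#'   `value`.
#' @export
timecourse_long <- function(tc) {
  if (inherits(tc, "fibrosis_run")) tc <- tc$timecourse
  if (!"seed" %in% names(tc)) tc <- cbind(seed = NA_integer_, tc)
  vars <- setdiff(names(tc), c("seed", "step"))
  out <- do.call(rbind, lapply(vars, function(v) {
    data.frame(seed = tc$seed, step = tc$step, variable = v, value = tc[[v]])
  }))
  rownames(out) <- NULL
  out
}
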