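#' Toxin injection schedule
#'
#' Describes when and how much CCl4 is injected.  Injections occur at
#' `first_step`, `first_step + interval`, ... up to `last_step`, unless
#' `n_injections` caps the count (in which case it overrides `last_step`).
#'
#' @param interval Steps between injections (>= 1).
#' @param dose Toxin mass per injection (>= 0, arbitrary units).
#' @param first_step Step of the first injection.
#' @param last_step No injections after this step.
#' @param n_injections Optional cap on the number of injections.
#' @return An object of class `injection_schedule`.
#' @export
injection_schedule <- function(interval, dose, first_step = 0L,
                               last_step = Inf, n_injections = NULL) {
  stopifnot(interval >= 1, dose >= 0)
  structure(list(interval = as.integer(interval), dose = dose,
                 first_step = as.integer(first_step), last_step = last_step,
                 n_injections = if (is.null(n_injections)) NULL
                                else as.integer(n_injections)),
            class = "injection_schedule")
}

#' Steps at which injections occur
#'
#' @param schedule An [injection_schedule()].
#' @param n_steps Horizon; only steps `< n_steps` are executed.
#' @return Integer vector of injection steps.
#' @examples
#' injection_steps(injection_schedule(10, 1), 40)     # 0 10 20 30
#' injection_steps(injection_schedule(10, 1, n_injections = 2), 100)  # 0 10
#' @export
injection_steps <- function(schedule, n_steps) {
  last <- min(schedule$last_step, n_steps - 1L)
  if (last < schedule$first_step) return(integer(0))
  steps <- seq(schedule$first_step, last, by = schedule$interval)
  if (!is.null(schedule$n_injections)) {
    steps <- utils::head(steps, schedule$n_injections)
  }
  as.integer(steps)
}

#' Apply the injection schedule at one step
#'
#' If `step` is an injection step, the dose is deposited across the lattice
#' proportionally to the zonation map (pericentral cells, where the toxin is
#' metabolically activated, receive more), normalised so that the total mass
#' added equals `dose`.  Otherwise the field is returned unchanged.
#'
#' @param step Current step index.
#' @param schedule An [injection_schedule()].
#' @param field The CCl4 `diffusible_field`.
#' @param zonation Zonation weight matrix (same dimensions as the field).
#' @return The (possibly updated) field.
#' @export
maybe_inject <- function(step, schedule, field, zonation) {
  horizon <- step + 1L
  if (!(step %in% injection_steps(schedule, horizon))) return(field)
  field$values <- field$values + schedule$dose * zonation / sum(zonation)
  field
}
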