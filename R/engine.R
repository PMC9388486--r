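#' Advance the simulation by one step
#'
#' Executes the per-step rule order: (a) toxin injection per the schedule;
#' (b) hepatocyte death checks (necrosis before apoptosis); (c) HMGB1 release
#' from necrotic dead cells; (d) Kupffer-cell replenishment and the
#' Kupffer-cell phase (movement, phagocytosis, activation, M1/M2 switch,
#' secretion); (e) stellate-cell activation; (f) collagen secretion by
#' fibroblasts; (g) hepatocyte proliferation; (h) ageing and lifespan
#' culling; (i) diffusion then decay of all four mediator fields.  The step
#' counter is incremented last.
#'
#' @param state A `lobule_state` from [build_lobule()].
#' @return The state after one step.
#' @export
sim_step <- function(state) {
  sched <- state$sched
  if (is.null(sched)) {
    s <- state$config$schedule
    sched <- injection_schedule(s$interval, s$dose, s$first_step, s$last_step,
                                s$n_injections)
  }
  state$fields$ccl4 <- maybe_inject(state$step, sched, state$fields$ccl4,
                                    state$zon)
  state <- hepatocyte_death_check(state)
  state <- hmgb1_release(state)
  state <- kupffer_replenish(state)
  state <- kupffer_step(state)
  state <- hsc_activation(state)
  state <- fibroblast_secrete(state)
  state <- hepatocyte_proliferate(state)
  state <- age_and_cull(state)
  for (f in names(state$fields)) {
    state$fields[[f]] <- decay_field(diffuse(state$fields[[f]]))
  }
  state$step <- state$step + 1L
  state
}

# one row of the time course
tally_state <- function(state) {
  occ <- state$occ
  dead <- occ == OCC_DEAD
  list(
    step = state$step,
    hepatocytes = sum(occ == OCC_HEP),
    dead_total = sum(dead),
    dead_necrotic = sum(state$dead_origin == DEAD_NECROTIC),
    dead_apoptotic = sum(state$dead_origin == DEAD_APOPTOTIC),
    kc_quiescent = sum(state$kc$state == KC_QUIESCENT),
    kc_activated = sum(state$kc$state != KC_QUIESCENT),
    hsc = length(state$hsc$pos),
    myofibroblasts = length(state$mfb$pos),
    portal_fibroblasts = length(state$pf$pos),
    collagen_mfb = sum(occ == OCC_COLLAGEN_MFB),
    collagen_pf = sum(occ == OCC_COLLAGEN_PF),
    blank = sum(occ == OCC_BLANK),
    ccl4_mass = sum(state$fields$ccl4$values),
    hmgb1_mass = sum(state$fields$hmgb1$values),
    tnf_mass = sum(state$fields$tnf$values),
    tgf_mass = sum(state$fields$tgf$values)
  )
}

#' Run a full simulation
#'
#' Builds the lobule from the configuration (seeding the RNG from
#' `config$seed`, so identical configurations yield bit-identical
#' trajectories), executes `n_steps` steps and records the complete time
#' course: one row per step from the initial state (step 0) to the final one.
#'
#' @param config A [sim_config()], or arguments forwarded to it.
#' @param check_invariants If `TRUE`, run the occupancy-exclusivity and field
#'   non-negativity scans after every step and stop on any violation (used by
#'   the validation suite; slows the run slightly).
#' @param ... If `config` is missing, arguments for [sim_config()].
#' @return An object of class `fibrosis_run`: a list with `timecourse` (a
#'   data frame, one row per recorded step), `snapshots` (named list of
#'   occupancy matrices at `snapshot_steps`), `final_state`, and `config`.
#' @examples
#' run <- simulate_lobule(sim_config(width = 41, height = 41, n_steps = 5,
#'                                   seed = 1))
#' head(run$timecourse[, 1:6])
#' @export
simulate_lobule <- function(config, check_invariants = FALSE, ...) {
  if (missing(config)) config <- sim_config(...)
  state <- build_lobule(config, seed_rng = TRUE)
  s <- config$schedule
  state$sched <- injection_schedule(s$interval, s$dose, s$first_step,
                                    s$last_step, s$n_injections)
  n <- config$n_steps
  rows <- vector("list", n + 1L)
  rows[[1L]] <- tally_state(state)
  snaps <- list()
  if (0L %in% config$snapshot_steps) snaps[["0"]] <- state$occ
  for (i in seq_len(n)) {
    state <- sim_step(state)
    rows[[i + 1L]] <- tally_state(state)
    if (check_invariants) {
      if (!scan_occupancy(state)) {
        stop("occupancy invariant violated at step ", state$step)
      }
      if (any(vapply(state$fields, function(f) any(f$values < 0), logical(1)))) {
        stop("negative field value at step ", state$step)
      }
    }
    if (state$step %in% config$snapshot_steps) {
      snaps[[as.character(state$step)]] <- state$occ
    }
  }
  tc <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  structure(list(timecourse = tc, snapshots = snaps,
                 final_state = state, config = config),
            class = "fibrosis_run")
}

#' @export
print.fibrosis_run <- function(x, ...) {
  tc <- x$timecourse
  last <- tc[nrow(tc), ]
  cat(sprintf("<fibrosis_run> %d steps on a %d x %d lobule (seed %d)\n",
              x$config$n_steps, x$config$geometry$height,
              x$config$geometry$width, x$config$seed))
  cat(sprintf("  final: hep %d, dead %d, activated KC %d, MFB %d, collagen %d (mfb) + %d (portal)\n",
              last$hepatocytes, last$dead_total, last$kc_activated,
              last$myofibroblasts, last$collagen_mfb, last$collagen_pf))
  invisible(x)
}

#' Run an ensemble of replicate simulations
#'
#' Runs the same configuration under several seeds and binds the time courses
#' into one long table with a `seed` column.
#'
#' @param config A [sim_config()]; its `seed` entry is replaced by each value
#'   of `seeds` in turn.
#' @param seeds Integer vector of seeds.
#' @return Data frame: the concatenated time courses, with `seed` first.
#' @export
run_ensemble <- function(config, seeds) {
  out <- lapply(seeds, function(s) {
    config$seed <- as.integer(s)
    tc <- simulate_lobule(config)$timecourse
    cbind(seed = s, tc)
  })
  do.call(rbind, out)
}
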