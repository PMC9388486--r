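#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_lobule()].  Every argument
#' has a default drawn from the packaged calibration ([default_calibration()])
#' and the default lobule geometry: a 101 x 101 lattice with one 3 x 3 central
#' vein block at the centre, four 3 x 3 portal tracts at the corners, and a
#' zonation weight `exp(-d / lambda)` of the Euclidean distance `d` to the
#' nearest central-vein site.
#'
#' Initial cell ratios follow the commonly observed composition of a lobule:
#' Kupffer cells 15% and stellate cells 5% of all placed cells, hepatocytes
#' filling every non-structural grid cell.
#'
#' @param width,height Lattice dimensions in cells (>= 20).
#' @param vein_centers List of `c(row, col)` centres of 3 x 3 central-vein
#'   blocks (1-based).
#' @param portal_centers List of `c(row, col)` centres of 3 x 3 portal-tract
#'   blocks (1-based).
#' @param lambda Zonation length scale in cells; default `width / 4`.
#' @param kc_ratio,hsc_ratio,mfb_ratio Initial fractions of all placed cells
#'   that are Kupffer cells, hepatic stellate cells and myofibroblasts.
#' @param interval Steps between toxin injections.
#' @param dose Toxin mass per injection (arbitrary units).
#' @param first_step Step of the first injection.
#' @param last_step No injections after this step; defaults to `n_steps`.
#' @param n_injections Optional cap on the number of injections; overrides
#'   `last_step` when set.
#' @param n_steps Number of simulation steps.
#' @param seed Integer RNG seed; the full trajectory is reproducible from it.
#' @param snapshot_steps Integer vector of steps at which to keep a copy of
#'   the occupancy lattice.
#' @param calibration Calibration list as produced by [default_calibration()];
#'   individual entries may be overridden.
#' @param ... Named calibration overrides merged into `calibration`
#'   (e.g. `thresholds = list(ccl4_hep = Inf)`); nested lists are merged
#'   element-wise.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_steps = 10, seed = 1)
#' cfg$schedule$interval
#' @export
sim_config <- function(width = 101L, height = 101L,
                       vein_centers = NULL, portal_centers = NULL,
                       lambda = NULL,
                       kc_ratio = 0.15, hsc_ratio = 0.05, mfb_ratio = 0,
                       interval = 10L, dose = NULL,
                       first_step = 0L, last_step = NULL, n_injections = NULL,
                       n_steps = 120L, seed = 1L,
                       snapshot_steps = integer(0),
                       calibration = default_calibration(), ...) {
  width <- as.integer(width); height <- as.integer(height)
  calibration <- modify_list_deep(calibration, list(...))
  if (is.null(vein_centers)) {
    vein_centers <- list(c((height + 1L) %/% 2L, (width + 1L) %/% 2L))
  }
  if (is.null(portal_centers)) {
    portal_centers <- list(c(2L, 2L), c(2L, width - 1L),
                           c(height - 1L, 2L), c(height - 1L, width - 1L))
  }
  if (is.null(lambda)) lambda <- width / 4
  if (is.null(dose)) dose <- calibration$dose
  if (is.null(last_step)) last_step <- n_steps

  cfg <- structure(list(
    geometry = list(width = width, height = height,
                    vein_centers = lapply(vein_centers, as.integer),
                    portal_centers = lapply(portal_centers, as.integer),
                    block_radius = 1L, lambda = lambda),
    initial_ratios = list(kc = kc_ratio, hsc = hsc_ratio, mfb = mfb_ratio),
    schedule = list(interval = as.integer(interval), dose = dose,
                    first_step = as.integer(first_step),
                    last_step = as.integer(last_step),
                    n_injections = if (is.null(n_injections)) NULL
                                   else as.integer(n_injections)),
    calibration = calibration,
    n_steps = as.integer(n_steps),
    seed = as.integer(seed),
    snapshot_steps = as.integer(snapshot_steps)
  ), class = "sim_config")
  validate_config(cfg)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<sim_config> %d x %d lobule, %d vein block(s), %d portal tract(s)\n",
              g$height, g$width, length(g$vein_centers), length(g$portal_centers)))
  cat(sprintf("  ratios: KC %.3g, HSC %.3g | injections: every %d steps, dose %.4g\n",
              x$initial_ratios$kc, x$initial_ratios$hsc,
              x$schedule$interval, x$schedule$dose))
  cat(sprintf("  n_steps %d, seed %d\n", x$n_steps, x$seed))
  invisible(x)
}

#' Validate a simulation configuration
#'
#' Checks geometry bounds, ratio sums, schedule sanity and calibration
#' non-negativity.  Called by [sim_config()]; exported so that configurations
#' read from file can be re-validated.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly; signals a condition of class
#'   `lobulefib_config_error` on any violation.
#' @export
validate_config <- function(cfg) {
  g <- cfg$geometry
  fail <- function(msg) stop(errorCondition(msg,
    class = c("lobulefib_config_error", "error")))
  if (g$width < 20L || g$height < 20L) {
    fail("lattice must be at least 20 x 20 cells")
  }
  if (length(g$vein_centers) < 1L) fail("at least one central vein is required")
  if (length(g$portal_centers) < 2L) fail("at least two portal tracts are required")
  blocks <- c(g$vein_centers, g$portal_centers)
  sites <- lapply(blocks, function(ctr) block_sites(ctr, g$block_radius, g$height, g$width))
  nv <- length(g$vein_centers)
  vein <- unique(do.call(rbind, sites[seq_len(nv)]))
  portal <- unique(do.call(rbind, sites[-seq_len(nv)]))
  key <- function(m) paste(m[, 1], m[, 2])
  if (any(key(vein) %in% key(portal))) {
    fail("central-vein and portal-tract sites overlap")
  }
  for (s in sites) {
    if (any(s[, 1] < 1L | s[, 1] > g$height | s[, 2] < 1L | s[, 2] > g$width)) {
      fail("structural block extends outside the lattice")
    }
  }
  r <- cfg$initial_ratios
  rs <- c(r$kc, r$hsc, r$mfb)
  if (any(rs < 0) || any(rs > 1)) fail("initial ratios must be in [0, 1]")
  if (sum(rs) >= 1) fail("initial ratios must sum to less than 100%")
  s <- cfg$schedule
  if (s$interval < 1L) fail("injection interval must be >= 1")
  if (s$dose < 0) fail("dose must be non-negative")
  if (cfg$n_steps < 0L) fail("n_steps must be non-negative")
  cal <- cfg$calibration
  for (f in names(cal$fields)) {
    p <- cal$fields[[f]]
    if (p$share < 0 || p$share > 1) fail(sprintf("share fraction of %s not in [0,1]", f))
    if (p$decay < 0 || p$decay >= 1) fail(sprintf("decay rate of %s not in [0,1)", f))
  }
  if (any(unlist(cal$secretion) < 0)) fail("secretion amounts must be non-negative")
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' The file holds any subset of the arguments of [sim_config()] as top-level
#' keys (`width`, `kc_ratio`, `interval`, ...) plus an optional `calibration`
#' block merged over the packaged defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated `sim_config`.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cal <- default_calibration()
  if (!is.null(raw$calibration)) {
    cal <- modify_list_deep(cal, raw$calibration)
    raw$calibration <- NULL
  }
  if (!is.null(raw$vein_centers)) raw$vein_centers <- lapply(raw$vein_centers, unlist)
  if (!is.null(raw$portal_centers)) raw$portal_centers <- lapply(raw$portal_centers, unlist)
  do.call(sim_config, c(raw, list(calibration = cal)))
}

# recursive utils::modifyList that merges nested lists element-wise
modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

# all (row, col) sites of a (2r+1) x (2r+1) structural block, clipped later
block_sites <- function(center, radius, height, width) {
  rows <- (center[1] - radius):(center[1] + radius)
  cols <- (center[2] - radius):(center[2] + radius)
  as.matrix(expand.grid(row = rows, col = cols))
}
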