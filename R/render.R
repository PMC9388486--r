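#' Snapshot colour style
#'
#' Colour semantics of rendered lobule snapshots: hepatocytes brown, dead
#' cells grey, myofibroblast-derived collagen blue, portal-fibroblast-derived
#' collagen green, plus distinct colours for the two vascular landmarks and
#' blank space.  When a non-occupying agent shares a cell with a
#' space-occupier, the occupier's colour wins: snapshots show the occupancy
#' layer only.
#'
#' @param scale Pixels per grid cell.
#' @param hide_hepatocytes Render hepatocyte cells in the blank colour, as in
#'   parenchyma-free views that expose the collagen pattern.
#' @param colors Optional named character vector overriding any of the seven
#'   class colours (`hepatocyte`, `dead`, `collagen_mfb`, `collagen_pf`,
#'   `vein`, `portal`, `blank`).
#' @return An object of class `snapshot_style`.
#' @export
snapshot_style <- function(scale = 1L, hide_hepatocytes = FALSE,
                           colors = character(0)) {
  base <- c(hepatocyte = "#8B5A2B", dead = "#9E9E9E",
            collagen_mfb = "#1F77B4", collagen_pf = "#2CA02C",
            vein = "#7F1D1D", portal = "#1A1A1A", blank = "#FFFFFF")
  base[names(colors)] <- colors
  if (anyDuplicated(base)) stop("snapshot colours must be distinct")
  structure(list(colors = base, scale = as.integer(scale),
                 hide_hepatocytes = isTRUE(hide_hepatocytes)),
            class = "snapshot_style")
}

#' Render a lobule snapshot
#'
#' Pure function of the occupancy lattice and a style: returns an RGB array
#' with one `scale` x `scale` pixel block per grid cell, row 1 at the top.
#'
#' @param grid A `lobule_state`, `fibrosis_run` (its final state), or a bare
#'   occupancy matrix.
#' @param style A [snapshot_style()].
#' @return Numeric array `height*scale` x `width*scale` x 3 with values in
#'   `[0, 1]`, suitable for [png::writePNG()].
#' @export
render_snapshot <- function(grid, style = snapshot_style()) {
  if (inherits(grid, "fibrosis_run")) grid <- grid$final_state
  occ <- if (is.list(grid)) grid$occ else grid
  cols <- style$colors
  codes <- occupancy_codes()
  map <- character(length(codes))
  map[codes + 1L] <- cols[names(codes)]
  if (style$hide_hepatocytes) map[OCC_HEP + 1L] <- cols[["blank"]]
  hex <- matrix(map[occ + 1L], nrow(occ), ncol(occ))
  rgb <- grDevices::col2rgb(hex) / 255
  img <- array(0, c(nrow(occ), ncol(occ), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(occ), ncol(occ))
  img[, , 2] <- matrix(rgb[2, ], nrow(occ), ncol(occ))
  img[, , 3] <- matrix(rgb[3, ], nrow(occ), ncol(occ))
  s <- style$scale
  if (s > 1L) {
    img <- img[rep(seq_len(nrow(occ)), each = s),
               rep(seq_len(ncol(occ)), each = s), , drop = FALSE]
  }
  img
}

#' Write a snapshot image
#'
#' @param img RGB array from [render_snapshot()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_snapshot_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Time-course and manifest input/output
#'
#' `write_timecourse()` / `read_timecourse()` round-trip a time-course table
#' through CSV; `write_manifest()` / `read_manifest()` round-trip the fully
#' resolved run configuration through JSON, so that any run can be reproduced
#' from its artefacts.
#'
#' @param tc Time-course data frame.
#' @param path File path.
#' @param run A `fibrosis_run` or a `sim_config` (the manifest records the
#'   resolved configuration).
#' @return The read functions return the parsed object; the write functions
#'   return `path` invisibly.
#' @export
write_timecourse <- function(tc, path) {
  utils::write.csv(tc, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  tc <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) {
                   stop("malformed time-course file '", path, "': ",
                        conditionMessage(e))
                 })
  tc
}

#' @rdname write_timecourse
#' @export
write_manifest <- function(run, path) {
  cfg <- if (inherits(run, "fibrosis_run")) run$config else run
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_manifest <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE,
                                      simplifyMatrix = FALSE),
                  error = function(e) {
                    stop("malformed manifest '", path, "': ",
                         conditionMessage(e))
                  })
  cfg <- structure(raw, class = "sim_config")
  cfg$geometry$vein_centers <- lapply(cfg$geometry$vein_centers, as.integer)
  cfg$geometry$portal_centers <- lapply(cfg$geometry$portal_centers, as.integer)
  for (nm in c("n_steps", "seed")) cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg$snapshot_steps <- as.integer(cfg$snapshot_steps)
  sc <- cfg$schedule
  cfg$schedule <- list(interval = as.integer(sc$interval), dose = sc$dose,
                       first_step = as.integer(sc$first_step),
                       last_step = as.integer(sc$last_step),
                       n_injections = if (is.null(sc$n_injections)) NULL
                                      else as.integer(sc$n_injections))
  validate_config(cfg)
  cfg
}
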