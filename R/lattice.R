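# Occupancy-layer codes.  Space-occupying classes exclude each other from a
# grid cell; Kupffer cells, HSCs, myofibroblasts and portal fibroblasts live
# in per-class registries and may share any cell.
OCC_BLANK  <- 0L
OCC_HEP    <- 1L
OCC_DEAD   <- 2L
OCC_COLLAGEN_MFB <- 3L
OCC_COLLAGEN_PF  <- 4L
OCC_VEIN   <- 5L
OCC_PORTAL <- 6L

DEAD_NONE      <- 0L
DEAD_NECROTIC  <- 1L
DEAD_APOPTOTIC <- 2L

KC_QUIESCENT <- 0L
KC_M1 <- 1L
KC_M2 <- 2L

#' Occupancy codes of the lobule lattice
#'
#' Named integer vector mapping occupancy-layer classes (blank, hepatocyte,
#' dead cell, the two collagen origins, central vein, portal tract) to the
#' codes stored in `state$occ`.
#'
#' @return Named integer vector.
#' @export
occupancy_codes <- function() {
  c(blank = OCC_BLANK, hepatocyte = OCC_HEP, dead = OCC_DEAD,
    collagen_mfb = OCC_COLLAGEN_MFB, collagen_pf = OCC_COLLAGEN_PF,
    vein = OCC_VEIN, portal = OCC_PORTAL)
}

#' Moore neighbourhood of a lattice position
#'
#' Returns the up-to-eight in-bounds neighbours of `pos` (no wrap-around:
#' the lattice is a lobule section with absorbing walls, not a torus).
#'
#' @param pos `c(row, col)`, 1-based.
#' @param dims `c(height, width)` of the lattice, or a lobule state, whose
#'   dimensions are used.
#' @return Integer matrix with columns `row`, `col`, one row per neighbour.
#' @examples
#' nrow(moore_neighbors(c(5, 5), c(9, 9)))  # interior: 8
#' nrow(moore_neighbors(c(1, 1), c(9, 9)))  # corner: 3
#' @export
moore_neighbors <- function(pos, dims) {
  if (is.list(dims)) dims <- c(dims$nr, dims$nc)
  r <- pos[1]; c <- pos[2]
  if (r < 1 || r > dims[1] || c < 1 || c > dims[2]) {
    stop("position out of bounds")
  }
  off <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  nb <- cbind(row = r + off[, 1], col = c + off[, 2])
  nb[nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2], ,
     drop = FALSE]
}

# Neighbour lookup table on linear (column-major) indices: nb_tab[i, 1:nb_n[i]]
# are the valid neighbours of cell i, packed left; nb_d holds their Euclidean
# distances (1 for orthogonal, sqrt(2) for diagonal).
build_neighbor_table <- function(nr, nc) {
  n <- nr * nc
  idx <- seq_len(n)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  off <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
  # order orthogonal first so distance-sorted scans are cheap
  dist <- sqrt(off[, 1]^2 + off[, 2]^2)
  off <- off[order(dist), , drop = FALSE]
  dist <- sort(dist)
  tab <- matrix(NA_integer_, n, 8)
  dtab <- matrix(NA_real_, n, 8)
  cnt <- integer(n)
  for (k in 1:8) {
    rr <- row + off[k, 1]; cc <- col + off[k, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    slot <- cnt + 1L
    lin <- (cc - 1L) * nr + rr
    tab[cbind(idx[ok], slot[ok])] <- lin[ok]
    dtab[cbind(idx[ok], slot[ok])] <- dist[k]
    cnt[ok] <- cnt[ok] + 1L
  }
  list(tab = tab, d = dtab, n = cnt)
}

#' Build the lobule lattice and place the initial cell population
#'
#' Constructs the structural geometry (central-vein and portal-tract blocks),
#' fills every remaining cell with a hepatocyte, computes the zonation map
#' `exp(-d / lambda)` from the distance to the nearest central-vein site, and
#' places Kupffer cells and stellate cells uniformly at random at the
#' configured ratios (expressed as fractions of all placed cells).  Portal
#' fibroblasts are placed one per cell on the ring of cells adjacent to each
#' portal tract.  Initialisation consumes the run RNG: the same `config$seed`
#' reproduces the same lobule bit-for-bit.
#'
#' @param config A [sim_config()].
#' @param seed_rng Seed the RNG from `config$seed` before placing agents
#'   (default `TRUE`; [simulate_lobule()] relies on this).
#' @return A `lobule_state` list: occupancy matrix `occ`, per-cell attribute
#'   matrices, zonation map `zon`, mediator fields, and the Kupffer / HSC /
#'   myofibroblast / portal-fibroblast registries.
#' @export
build_lobule <- function(config, seed_rng = TRUE) {
  validate_config(config)
  if (seed_rng) set.seed(config$seed)
  g <- config$geometry
  nr <- g$height; nc <- g$width
  n <- nr * nc
  occ <- matrix(OCC_HEP, nr, nc)

  vein_sites <- unique(do.call(rbind, lapply(g$vein_centers, block_sites,
                                             radius = g$block_radius,
                                             height = nr, width = nc)))
  portal_sites <- unique(do.call(rbind, lapply(g$portal_centers, block_sites,
                                               radius = g$block_radius,
                                               height = nr, width = nc)))
  occ[cbind(vein_sites[, 1], vein_sites[, 2])] <- OCC_VEIN
  occ[cbind(portal_sites[, 1], portal_sites[, 2])] <- OCC_PORTAL

  # zonation: min Euclidean distance to any central-vein site
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dmin <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(vein_sites))) {
    d <- sqrt((row - vein_sites[i, 1])^2 + (col - vein_sites[i, 2])^2)
    dmin <- pmin(dmin, d)
  }
  zon <- exp(-dmin / g$lambda)

  nbt <- build_neighbor_table(nr, nc)

  cal <- config$calibration
  f <- cal$fields
  fields <- list(
    ccl4  = new_field("ccl4",  nr, nc, f$ccl4$share,  f$ccl4$decay),
    hmgb1 = new_field("hmgb1", nr, nc, f$hmgb1$share, f$hmgb1$decay),
    tnf   = new_field("tnf",   nr, nc, f$tnf$share,   f$tnf$decay),
    tgf   = new_field("tgf",   nr, nc, f$tgf$share,   f$tgf$decay)
  )

  n_hep <- sum(occ == OCC_HEP)
  r <- config$initial_ratios
  denom <- 1 - r$kc - r$hsc - r$mfb
  n_kc  <- round(n_hep * r$kc  / denom)
  n_hsc <- round(n_hep * r$hsc / denom)
  n_mfb <- round(n_hep * r$mfb / denom)

  kc_life <- cal$lifespans$kupffer
  kc <- list(pos = sample.int(n, n_kc, replace = TRUE),
             state = rep(KC_QUIESCENT, n_kc),
             age = if (n_kc > 0) sample.int(max(kc_life, 1L), n_kc, replace = TRUE) - 1L
                   else integer(0),
             since = rep(NA_integer_, n_kc))
  hsc <- list(pos = sample.int(n, n_hsc, replace = TRUE),
              age = integer(n_hsc))
  mfb <- list(pos = sample.int(n, n_mfb, replace = TRUE),
              age = integer(n_mfb), produced = integer(n_mfb))

  # portal fibroblasts: one per ring cell adjacent to each portal tract
  pf_pos <- integer(0)
  for (ctr in g$portal_centers) {
    blk <- block_sites(ctr, g$block_radius, nr, nc)
    ring <- block_sites(ctr, g$block_radius + 1L, nr, nc)
    key <- paste(ring[, 1], ring[, 2])
    ring <- ring[!(key %in% paste(blk[, 1], blk[, 2])), , drop = FALSE]
    ok <- ring[, 1] >= 1L & ring[, 1] <= nr & ring[, 2] >= 1L & ring[, 2] <= nc
    ring <- ring[ok, , drop = FALSE]
    pf_pos <- c(pf_pos, (ring[, 2] - 1L) * nr + ring[, 1])
  }
  pf_pos <- setdiff(pf_pos, which(occ == OCC_VEIN | occ == OCC_PORTAL))
  pf <- list(pos = pf_pos, age = integer(length(pf_pos)))

  state <- list(
    config = config, step = 0L, nr = nr, nc = nc,
    occ = occ,
    hep_age = matrix(0L, nr, nc),
    hep_cd  = matrix(0L, nr, nc),
    dead_origin = matrix(DEAD_NONE, nr, nc),
    dead_age    = matrix(0L, nr, nc),
    zon = zon, zon_norm = zon / sum(zon),
    vein_sites = vein_sites, portal_sites = portal_sites,
    portal_blocks = lapply(g$portal_centers, function(ctr) {
      blk <- block_sites(ctr, g$block_radius, nr, nc)
      (blk[, 2] - 1L) * nr + blk[, 1]
    }),
    nb = nbt,
    fields = fields,
    kc = kc, hsc = hsc, mfb = mfb, pf = pf,
    initial_counts = list(hepatocyte = n_hep, kc = n_kc, hsc = n_hsc,
                          mfb = n_mfb, pf = length(pf_pos))
  )
  class(state) <- "lobule_state"
  state
}

#' @export
print.lobule_state <- function(x, ...) {
  cat(sprintf("<lobule_state> %d x %d, step %d\n", x$nr, x$nc, x$step))
  tc <- tally_state(x)
  cat(sprintf("  hep %d | dead %d | KC %d (%d act) | HSC %d | MFB %d | collagen %d+%d\n",
              tc$hepatocytes, tc$dead_total, tc$kc_quiescent + tc$kc_activated,
              tc$kc_activated, tc$hsc, tc$myofibroblasts,
              tc$collagen_mfb, tc$collagen_pf))
  invisible(x)
}

#' Occupancy queries and placement
#'
#' `is_vacant()` reports whether the occupancy layer at `pos` is blank;
#' `occupant()` returns the occupancy class name.  `place_agent()` puts a
#' space-occupying agent (`"hepatocyte"`, `"dead"`, `"collagen_mfb"`,
#' `"collagen_pf"`) on a vacant cell, or registers a non-occupying agent
#' (`"kc"`, `"hsc"`, `"myofibroblast"`, `"portal_fibroblast"`) at any cell;
#' `remove_agent()` frees a cell of its space-occupying agent.
#'
#' @param state A `lobule_state`.
#' @param pos `c(row, col)`, 1-based.
#' @param type Agent class name.
#' @return `is_vacant()`: logical; `occupant()`: character; the others return
#'   the modified state.  Placing a space-occupying agent on an occupied cell
#'   signals an error of class `lobulefib_occupancy_error`.
#' @export
is_vacant <- function(state, pos) {
  state$occ[pos[1], pos[2]] == OCC_BLANK
}

#' @rdname is_vacant
#' @export
occupant <- function(state, pos) {
  codes <- occupancy_codes()
  names(codes)[match(state$occ[pos[1], pos[2]], codes)]
}

#' @rdname is_vacant
#' @export
place_agent <- function(state, pos, type) {
  lin <- (pos[2] - 1L) * state$nr + pos[1]
  occupiers <- c(hepatocyte = OCC_HEP, dead = OCC_DEAD,
                 collagen_mfb = OCC_COLLAGEN_MFB, collagen_pf = OCC_COLLAGEN_PF)
  if (type %in% names(occupiers)) {
    if (state$occ[lin] != OCC_BLANK) {
      stop(errorCondition(
        sprintf("cell (%d, %d) already holds a space-occupying agent (%s)",
                pos[1], pos[2], occupant(state, pos)),
        class = c("lobulefib_occupancy_error", "error")))
    }
    state$occ[lin] <- occupiers[[type]]
    if (type == "hepatocyte") {
      state$hep_age[lin] <- 0L; state$hep_cd[lin] <- 0L
    } else if (type == "dead") {
      state$dead_origin[lin] <- DEAD_NECROTIC; state$dead_age[lin] <- 0L
    }
  } else if (type == "kc") {
    state$kc$pos <- c(state$kc$pos, lin)
    state$kc$state <- c(state$kc$state, KC_QUIESCENT)
    state$kc$age <- c(state$kc$age, 0L)
    state$kc$since <- c(state$kc$since, NA_integer_)
  } else if (type == "hsc") {
    state$hsc$pos <- c(state$hsc$pos, lin)
    state$hsc$age <- c(state$hsc$age, 0L)
  } else if (type == "myofibroblast") {
    state$mfb$pos <- c(state$mfb$pos, lin)
    state$mfb$age <- c(state$mfb$age, 0L)
    state$mfb$produced <- c(state$mfb$produced, 0L)
  } else if (type == "portal_fibroblast") {
    state$pf$pos <- c(state$pf$pos, lin)
    state$pf$age <- c(state$pf$age, 0L)
  } else {
    stop("unknown agent type: ", type)
  }
  state
}

#' @rdname is_vacant
#' @export
remove_agent <- function(state, pos) {
  lin <- (pos[2] - 1L) * state$nr + pos[1]
  if (state$occ[lin] %in% c(OCC_VEIN, OCC_PORTAL)) {
    stop("structural sites cannot be removed")
  }
  state$occ[lin] <- OCC_BLANK
  state$dead_origin[lin] <- DEAD_NONE
  state
}

# occupancy-layer exclusivity scan used by tests and check_invariants runs
scan_occupancy <- function(state) {
  codes <- c(OCC_BLANK, OCC_HEP, OCC_DEAD, OCC_COLLAGEN_MFB, OCC_COLLAGEN_PF,
             OCC_VEIN, OCC_PORTAL)
  all(state$occ %in% codes) &&
    all(state$dead_origin[state$occ == OCC_DEAD] != DEAD_NONE) &&
    all(state$dead_origin[state$occ != OCC_DEAD] == DEAD_NONE)
}
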