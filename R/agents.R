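# Agent update rules.  Each function implements one phase of the step loop on
# a whole lobule_state and returns the updated state; the engine calls them in
# a fixed order (see sim_step).  All randomness flows through the run RNG.

#' Hepatocyte death check
#'
#' A hepatocyte dies when the effective toxin concentration — CCl4 weighted by
#' the local zonation (metabolic-activation) weight — exceeds the necrosis
#' threshold, producing a necrotic dead cell in place, or, failing that, when
#' TNF-alpha exceeds the apoptosis threshold, producing an apoptotic dead
#' cell.  The toxin test takes precedence: when both mediators are above
#' threshold the death is labelled necrotic.  Applied to every hepatocyte on
#' the lattice with a single shared field snapshot, so scan order cannot
#' matter.
#'
#' @param state A `lobule_state`.
#' @return Updated state.
#' @export
hepatocyte_death_check <- function(state) {
  th <- state$config$calibration$thresholds
  hep <- state$occ == OCC_HEP
  eff <- state$fields$ccl4$values * state$zon
  nec <- hep & (eff > th$ccl4_hep)
  apo <- hep & !nec & (state$fields$tnf$values > th$tnf_hep)
  died <- nec | apo
  if (any(died)) {
    state$occ[died] <- OCC_DEAD
    state$dead_origin[nec] <- DEAD_NECROTIC
    state$dead_origin[apo] <- DEAD_APOPTOTIC
    state$dead_age[died] <- 0L
  }
  state
}

# necrotic (and only necrotic) dead cells release the DAMP HMGB1 each step
hmgb1_release <- function(state) {
  idx <- which(state$occ == OCC_DEAD & state$dead_origin == DEAD_NECROTIC)
  if (length(idx)) {
    amt <- state$config$calibration$secretion$hmgb1
    state$fields$hmgb1$values[idx] <- state$fields$hmgb1$values[idx] + amt
  }
  state
}

#' Kupffer-cell replenishment from the portal area
#'
#' With probability `rate` per portal tract per step, a new quiescent Kupffer
#' cell (a monocyte-derived macrophage recruited from circulating blood)
#' appears on a uniformly chosen site of that tract.
#'
#' @param state A `lobule_state`.
#' @param rate Bernoulli probability per tract per step; defaults to the
#'   calibrated value.
#' @return Updated state.
#' @export
kupffer_replenish <- function(state, rate = NULL) {
  if (is.null(rate)) rate <- state$config$calibration$kc_replenish_rate
  for (blk in state$portal_blocks) {
    if (stats::runif(1) < rate) {
      site <- blk[sample.int(length(blk), 1L)]
      state$kc$pos <- c(state$kc$pos, site)
      state$kc$state <- c(state$kc$state, KC_QUIESCENT)
      state$kc$age <- c(state$kc$age, 0L)
      state$kc$since <- c(state$kc$since, NA_integer_)
    }
  }
  state
}

#' Kupffer-cell phase: movement, phagocytosis, activation, secretion
#'
#' Every Kupffer cell (i) moves to a uniformly chosen in-bounds Moore
#' neighbour; (ii) if a dead cell lies on its cell, phagocytoses it — the dead
#' cell disappears and the space becomes blank — and, if quiescent, becomes
#' M1; when several KCs land on the same dead cell, one of them (uniformly
#' chosen) performs the phagocytosis; (iii) if still quiescent and the local
#' HMGB1 concentration exceeds the activation threshold, becomes M1; (iv) M1
#' cells that were activated `tau_m1m2` or more steps ago switch to M2; then
#' (v) each M1 deposits `secretion$tnf` of TNF-alpha and each M2 deposits
#' `secretion$tgf` of TGF-beta into its cell.  HMGB1 is read from a snapshot
#' taken at the start of the phase.
#'
#' @param state A `lobule_state`.
#' @return Updated state.
#' @export
kupffer_step <- function(state) {
  n <- length(state$kc$pos)
  if (n == 0L) return(state)
  cal <- state$config$calibration
  hmgb1_snapshot <- state$fields$hmgb1$values

  # (i) undirected random movement, exact-uniform over in-bounds neighbours
  pos <- state$kc$pos
  k <- floor(stats::runif(n) * state$nb$n[pos]) + 1L
  pos <- state$nb$tab[cbind(pos, k)]
  state$kc$pos <- pos

  # (ii) phagocytosis: one KC per dead cell, uniformly chosen
  on_dead <- which(state$occ[pos] == OCC_DEAD)
  if (length(on_dead)) {
    ord <- on_dead[sample.int(length(on_dead))]
    eater <- ord[!duplicated(pos[ord])]
    cells <- pos[eater]
    state$occ[cells] <- OCC_BLANK
    state$dead_origin[cells] <- DEAD_NONE
    newly <- eater[state$kc$state[eater] == KC_QUIESCENT]
    state$kc$state[newly] <- KC_M1
    state$kc$since[newly] <- 0L
  }

  # (iii) DAMP-mediated activation of still-quiescent KCs
  quiet <- which(state$kc$state == KC_QUIESCENT)
  hot <- quiet[hmgb1_snapshot[pos[quiet]] > cal$thresholds$hmgb1_kc]
  if (length(hot)) {
    state$kc$state[hot] <- KC_M1
    state$kc$since[hot] <- 0L
  }

  # (iv) M1 -> M2 phenotype switch
  to_m2 <- which(state$kc$state == KC_M1 & state$kc$since >= cal$tau_m1m2)
  if (length(to_m2)) state$kc$state[to_m2] <- KC_M2

  # (v) secretion: M1 -> TNF-alpha, M2 -> TGF-beta
  ncell <- state$nr * state$nc
  m1 <- pos[state$kc$state == KC_M1]
  if (length(m1)) {
    state$fields$tnf$values <- state$fields$tnf$values +
      cal$secretion$tnf * tabulate(m1, nbins = ncell)
  }
  m2 <- pos[state$kc$state == KC_M2]
  if (length(m2)) {
    state$fields$tgf$values <- state$fields$tgf$values +
      cal$secretion$tgf * tabulate(m2, nbins = ncell)
  }
  state
}

#' Stellate-cell activation
#'
#' Every hepatic stellate cell whose local TNF-alpha concentration exceeds the
#' transformation threshold is replaced, in place, by a myofibroblast (age 0,
#' no collagen produced yet).  Neither HSCs nor myofibroblasts ever move.
#'
#' @param state A `lobule_state`.
#' @return Updated state.
#' @export
hsc_activation <- function(state) {
  if (!length(state$hsc$pos)) return(state)
  th <- state$config$calibration$thresholds$tnf_hsc
  conv <- state$fields$tnf$values[state$hsc$pos] > th
  if (any(conv)) {
    state$mfb$pos <- c(state$mfb$pos, state$hsc$pos[conv])
    state$mfb$age <- c(state$mfb$age, integer(sum(conv)))
    state$mfb$produced <- c(state$mfb$produced, integer(sum(conv)))
    state$hsc$pos <- state$hsc$pos[!conv]
    state$hsc$age <- state$hsc$age[!conv]
  }
  state
}

#' Collagen secretion by myofibroblasts and portal fibroblasts
#'
#' Each fibroblast whose local TGF-beta concentration exceeds the secretion
#' threshold places one collagen deposit, tagged with its origin, in the
#' nearest vacant cell: its own cell if blank, otherwise the nearest vacant
#' Moore neighbour (orthogonal before diagonal, ties broken uniformly at
#' random); if no vacancy exists the attempt is skipped this step.
#' Myofibroblasts count their deposits and are removed once they reach
#' `max_collagen_per_mfb` (they die upon collagen production); portal
#' fibroblasts persist indefinitely.  Producers act in a uniformly shuffled
#' order, against a TGF-beta snapshot taken at the start of the phase.
#'
#' @param state A `lobule_state`.
#' @return Updated state.
#' @export
fibroblast_secrete <- function(state) {
  cal <- state$config$calibration
  tgf <- state$fields$tgf$values
  th <- cal$thresholds$tgf_fib
  act_m <- which(tgf[state$mfb$pos] > th)
  act_p <- which(tgf[state$pf$pos] > th)
  n_act <- length(act_m) + length(act_p)
  if (n_act == 0L) return(state)
  is_mfb <- c(rep(TRUE, length(act_m)), rep(FALSE, length(act_p)))
  id <- c(act_m, act_p)
  ord <- sample.int(n_act)
  kill_mfb <- integer(0)
  for (i in ord) {
    p0 <- if (is_mfb[i]) state$mfb$pos[id[i]] else state$pf$pos[id[i]]
    if (state$occ[p0] == OCC_BLANK) {
      target <- p0
    } else {
      nn <- state$nb$n[p0]
      nbrs <- state$nb$tab[p0, seq_len(nn)]
      vac <- state$occ[nbrs] == OCC_BLANK
      if (!any(vac)) next
      d <- state$nb$d[p0, seq_len(nn)][vac]
      cand <- nbrs[vac][d == min(d)]
      target <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
    }
    state$occ[target] <- if (is_mfb[i]) OCC_COLLAGEN_MFB else OCC_COLLAGEN_PF
    if (is_mfb[i]) {
      state$mfb$produced[id[i]] <- state$mfb$produced[id[i]] + 1L
      if (state$mfb$produced[id[i]] >= cal$max_collagen_per_mfb) {
        kill_mfb <- c(kill_mfb, id[i])
      }
    }
  }
  if (length(kill_mfb)) {
    keep <- setdiff(seq_along(state$mfb$pos), kill_mfb)
    state$mfb$pos <- state$mfb$pos[keep]
    state$mfb$age <- state$mfb$age[keep]
    state$mfb$produced <- state$mfb$produced[keep]
  }
  state
}

#' Hepatocyte proliferation
#'
#' Hepatocytes monitor their Moore neighbourhood and replicate into a vacant
#' neighbour, chosen uniformly at random, provided (i) their replication
#' cooldown has expired and (ii) the neighbourhood is not collagen-rich
#' (fewer than `collagen_rich_threshold` collagen deposits among the
#' neighbours).  Division starts the cooldown on both parent and daughter.
#' Candidate parents act in a uniformly shuffled order, so two parents never
#' fill the same vacancy.
#'
#' @param state A `lobule_state`.
#' @return Updated state.
#' @export
hepatocyte_proliferate <- function(state) {
  blanks <- which(state$occ == OCC_BLANK)
  if (!length(blanks)) return(state)
  cal <- state$config$calibration
  # parents: ready hepatocytes adjacent to at least one blank
  nbr_of_blank <- state$nb$tab[blanks, , drop = FALSE]
  cand <- unique(nbr_of_blank[!is.na(nbr_of_blank)])
  cand <- cand[state$occ[cand] == OCC_HEP & state$hep_cd[cand] == 0L]
  if (!length(cand)) return(state)
  cand <- cand[sample.int(length(cand))]
  cd <- cal$replication_cooldown
  crt <- cal$collagen_rich_threshold
  for (p in cand) {
    nn <- state$nb$n[p]
    nbrs <- state$nb$tab[p, seq_len(nn)]
    occn <- state$occ[nbrs]
    vac <- nbrs[occn == OCC_BLANK]
    if (!length(vac)) next
    if (sum(occn == OCC_COLLAGEN_MFB | occn == OCC_COLLAGEN_PF) >= crt) next
    child <- if (length(vac) == 1L) vac else vac[sample.int(length(vac), 1L)]
    state$occ[child] <- OCC_HEP
    state$hep_age[child] <- 0L
    state$hep_cd[child] <- cd
    state$hep_cd[p] <- cd
  }
  state
}

#' Ageing and lifespan culling
#'
#' Every agent's age is incremented; agents at or beyond their class lifespan
#' are removed (space-occupiers leave a blank).  Collagen deposits are never
#' removed — the model has no fibrosis-regression process.  Replication
#' cooldowns tick down and activated Kupffer cells advance their
#' time-since-activation counter here.
#'
#' @param state A `lobule_state`.
#' @return Updated state.
#' @export
age_and_cull <- function(state) {
  ls <- state$config$calibration$lifespans
  hep <- state$occ == OCC_HEP
  state$hep_age[hep] <- state$hep_age[hep] + 1L
  old <- hep & state$hep_age >= ls$hepatocyte
  if (any(old)) state$occ[old] <- OCC_BLANK

  dead <- state$occ == OCC_DEAD
  state$dead_age[dead] <- state$dead_age[dead] + 1L
  gone <- dead & state$dead_age >= ls$dead
  if (any(gone)) {
    state$occ[gone] <- OCC_BLANK
    state$dead_origin[gone] <- DEAD_NONE
  }

  state$hep_cd <- pmax(state$hep_cd - 1L, 0L)

  state$kc$age <- state$kc$age + 1L
  act <- !is.na(state$kc$since)
  state$kc$since[act] <- state$kc$since[act] + 1L
  keep <- state$kc$age < ls$kupffer
  if (!all(keep)) state$kc <- lapply(state$kc, `[`, keep)

  state$hsc$age <- state$hsc$age + 1L
  keep <- state$hsc$age < ls$hsc
  if (!all(keep)) state$hsc <- lapply(state$hsc, `[`, keep)

  state$mfb$age <- state$mfb$age + 1L
  keep <- state$mfb$age < ls$myofibroblast
  if (!all(keep)) state$mfb <- lapply(state$mfb, `[`, keep)

  state$pf$age <- state$pf$age + 1L
  keep <- state$pf$age < ls$portal_fibroblast
  if (!all(keep)) state$pf <- lapply(state$pf, `[`, keep)

  state
}
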