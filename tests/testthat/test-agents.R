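test_that("hepatocyte death: toxin necrosis takes precedence over apoptosis", {
  st <- build_lobule(tiny_config())
  codes <- occupancy_codes()
  # both mediators zero: everyone survives
  st1 <- hepatocyte_death_check(st)
  expect_identical(st1$occ, st$occ)

  # effective toxin above threshold at a zonation~1 cell -> necrosis
  hot <- c(11L, 13L)  # adjacent to the vein block, zonation ~ 1
  st2 <- poke_field(st, "ccl4", hot, 2)
  st2 <- hepatocyte_death_check(st2)
  expect_identical(occupant(st2, hot), "dead")
  expect_identical(st2$dead_origin[hot[1], hot[2]], 1L)  # necrotic

  # toxin below, TNF above -> apoptosis
  st3 <- poke_field(st, "tnf", hot, 2)
  st3 <- hepatocyte_death_check(st3)
  expect_identical(st3$dead_origin[hot[1], hot[2]], 2L)  # apoptotic

  # both above -> the necrosis label wins
  st4 <- poke_field(poke_field(st, "ccl4", hot, 2), "tnf", hot, 9)
  st4 <- hepatocyte_death_check(st4)
  expect_identical(st4$dead_origin[hot[1], hot[2]], 1L)

  # zonation shields the periphery: same concentration, edge cell survives
  st5 <- poke_field(st, "ccl4", c(1L, 11L), 2)
  st5 <- hepatocyte_death_check(st5)
  expect_identical(occupant(st5, c(1L, 11L)), "hepatocyte")
})

test_that("only necrotic dead cells release HMGB1", {
  st <- build_lobule(tiny_config())
  st <- poke_field(st, "ccl4", c(11L, 13L), 2)   # -> necrosis
  st <- poke_field(st, "tnf", c(5L, 5L), 2)      # -> apoptosis
  st <- hepatocyte_death_check(st)
  st <- lobulefib:::hmgb1_release(st)
  amt <- st$config$calibration$secretion$hmgb1
  expect_equal(st$fields$hmgb1$values[11, 13], amt)
  expect_equal(st$fields$hmgb1$values[5, 5], 0)
  expect_equal(field_total(st$fields$hmgb1), amt)
})

test_that("kupffer cells move, phagocytose, activate and switch phenotype", {
  set.seed(1)
  st <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  # one quiescent KC at (6,6); every Moore neighbour holds a dead cell, so the
  # move lands on a dead cell wherever it goes
  st$kc <- list(pos = lin_index(st, c(6L, 6L)), state = 0L, age = 0L,
                since = NA_integer_)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) {
      p <- c(6L + dr, 6L + dc)
      st <- place_agent(remove_agent(st, p), p, "dead")
    }
  }
  n_dead0 <- sum(st$occ == occupancy_codes()[["dead"]])
  st1 <- kupffer_step(st)
  expect_equal(sum(st1$occ == occupancy_codes()[["dead"]]), n_dead0 - 1)
  expect_identical(st1$kc$state, 1L)          # activated by phagocytosis
  expect_identical(st1$kc$since, 0L)
  # the vacated cell is blank and the KC deposited TNF at its new position
  expect_equal(field_total(st1$fields$tnf),
               st$config$calibration$secretion$tnf)

  # quiescent KC with no dead cell and HMGB1 below threshold stays quiescent
  st2 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  st2$kc <- list(pos = lin_index(st2, c(6L, 6L)), state = 0L, age = 0L,
                 since = NA_integer_)
  st2a <- kupffer_step(st2)
  expect_identical(st2a$kc$state, 0L)
  expect_equal(field_total(st2a$fields$tnf), 0)

  # HMGB1 above threshold activates in place
  th <- st2$config$calibration$thresholds$hmgb1_kc
  st2$fields$hmgb1$values[] <- th * 1.01
  st2b <- kupffer_step(st2)
  expect_identical(st2b$kc$state, 1L)

  # M1 activated exactly tau steps ago switches to M2 and secretes TGF-beta
  st3 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  tau <- st3$config$calibration$tau_m1m2
  st3$kc <- list(pos = lin_index(st3, c(6L, 6L)), state = 1L, age = 10L,
                 since = as.integer(tau))
  st3 <- kupffer_step(st3)
  expect_identical(st3$kc$state, 2L)
  expect_equal(field_total(st3$fields$tgf),
               st3$config$calibration$secretion$tgf)
  expect_equal(field_total(st3$fields$tnf), 0)
})

test_that("portal replenishment follows the Bernoulli rate", {
  st <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  # rate 1, 4 tracts, 10 steps -> exactly 40 quiescent KCs on tract sites
  for (i in 1:10) st <- kupffer_replenish(st, rate = 1)
  expect_length(st$kc$pos, 40)
  expect_true(all(st$kc$state == 0L))
  expect_true(all(st$kc$pos %in% unlist(st$portal_blocks)))
  # rate 0 adds none over any horizon
  st0 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  for (i in 1:25) st0 <- kupffer_replenish(st0, rate = 0)
  expect_length(st0$kc$pos, 0)
  # rate 0.5, one would-be tract draw per tract per step: binomial mean
  set.seed(5)
  st5 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  for (i in 1:250) st5 <- kupffer_replenish(st5, rate = 0.5)
  expect_lt(abs(length(st5$kc$pos) - 500), 4 * sqrt(1000 * 0.25))
})

test_that("stellate cells transform in place when TNF-alpha crosses threshold", {
  st <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  th <- st$config$calibration$thresholds$tnf_hsc
  st$hsc <- list(pos = c(lin_index(st, c(4L, 4L)), lin_index(st, c(15L, 15L))),
                 age = c(3L, 3L))
  st <- poke_field(st, "tnf", c(4L, 4L), th * 1.01)
  st1 <- hsc_activation(st)
  expect_length(st1$hsc$pos, 1)
  expect_length(st1$mfb$pos, 1)
  expect_equal(st1$mfb$pos, lin_index(st, c(4L, 4L)))  # same position
  expect_equal(st1$mfb$age, 0L)
  # TNF at zero: nothing converts
  st2 <- hsc_activation(build_lobule(tiny_config()))
  expect_length(st2$mfb$pos, 0)
})

test_that("fibroblasts deposit origin-tagged collagen; myofibroblasts die of it", {
  st <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0,
                                 max_collagen_per_mfb = 1L))
  codes <- occupancy_codes()
  # myofibroblast on an occupied cell with one vacant neighbour
  mpos <- c(7L, 7L); vac <- c(7L, 8L)
  st$mfb <- list(pos = lin_index(st, mpos), age = 0L, produced = 0L)
  st <- remove_agent(st, vac)
  st$fields$tgf$values[] <- 2  # everywhere above threshold
  st1 <- fibroblast_secrete(st)
  expect_identical(st1$occ[vac[1], vac[2]], codes[["collagen_mfb"]])
  expect_length(st1$mfb$pos, 0)  # died upon collagen production (cap 1)

  # portal fibroblast persists after producing, with its own origin tag
  st2 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  ppos <- c(3L, 5L)
  st2$pf <- list(pos = lin_index(st2, ppos), age = 0L)
  st2 <- remove_agent(st2, ppos)          # its own cell is vacant
  st2$fields$tgf$values[] <- 2
  st2a <- fibroblast_secrete(st2)
  expect_identical(st2a$occ[ppos[1], ppos[2]], codes[["collagen_pf"]])
  expect_length(st2a$pf$pos, 1)

  # TGF-beta at zero, or no vacancy anywhere nearby: no deposit
  st3 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  st3$mfb <- list(pos = lin_index(st3, mpos), age = 0L, produced = 0L)
  expect_equal(sum(fibroblast_secrete(st3)$occ == codes[["collagen_mfb"]]), 0)
  st3$fields$tgf$values[] <- 2
  st3a <- fibroblast_secrete(st3)         # fully packed neighbourhood
  expect_equal(sum(st3a$occ == codes[["collagen_mfb"]]), 0)
  expect_length(st3a$mfb$pos, 1)

  # nearest-vacancy rule: own cell beats any neighbour
  st4 <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  st4$mfb <- list(pos = lin_index(st4, mpos), age = 0L, produced = 0L)
  st4 <- remove_agent(st4, mpos)
  st4 <- remove_agent(st4, vac)
  st4$fields$tgf$values[] <- 2
  st4a <- fibroblast_secrete(st4)
  expect_identical(st4a$occ[mpos[1], mpos[2]], codes[["collagen_mfb"]])
  expect_true(is_vacant(st4a, vac))
})

test_that("hepatocytes fill vacancies unless the neighbourhood is collagen-rich", {
  set.seed(2)
  codes <- occupancy_codes()
  # fully surrounded: nothing happens
  st <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0))
  expect_identical(hepatocyte_proliferate(st)$occ, st$occ)

  # one vacancy, no collagen: filled by a neighbour
  st1 <- remove_agent(st, c(8L, 8L))
  st1a <- hepatocyte_proliferate(st1)
  expect_identical(st1a$occ[8, 8], codes[["hepatocyte"]])
  expect_equal(st1a$hep_cd[8, 8], st$config$calibration$replication_cooldown)

  # collagen-rich ring blocks every candidate parent
  st2 <- remove_agent(st, c(8L, 8L))
  for (p in list(c(7L, 7L), c(7L, 8L), c(7L, 9L), c(9L, 7L), c(9L, 8L),
                 c(9L, 9L), c(8L, 6L), c(8L, 10L), c(6L, 6L), c(6L, 7L),
                 c(6L, 8L), c(6L, 9L), c(6L, 10L), c(10L, 6L), c(10L, 7L),
                 c(10L, 8L), c(10L, 9L), c(10L, 10L), c(7L, 6L), c(7L, 10L),
                 c(9L, 6L), c(9L, 10L))) {
    st2$occ[p[1], p[2]] <- codes[["collagen_mfb"]]
  }
  # the vacancy's only hepatocyte neighbours now all see >= 3 collagen deposits
  st2a <- hepatocyte_proliferate(st2)
  expect_identical(st2a$occ[8, 8], codes[["blank"]])

  # parents on cooldown do not divide
  st3 <- remove_agent(st, c(8L, 8L))
  st3$hep_cd[] <- 5L
  expect_identical(hepatocyte_proliferate(st3)$occ[8, 8], codes[["blank"]])
})

test_that("ageing removes agents exactly at their lifespan", {
  st <- build_lobule(tiny_config(kc_ratio = 0, hsc_ratio = 0,
                                 lifespans = list(dead = 5L)))
  st <- remove_agent(st, c(4L, 9L))
  st <- place_agent(st, c(4L, 9L), "dead")
  st$hsc <- list(pos = lin_index(st, c(12L, 3L)), age = 0L)
  dead_code <- occupancy_codes()[["dead"]]
  present <- integer(0)
  for (i in 1:6) {
    present <- c(present, sum(st$occ == dead_code))
    st <- age_and_cull(st)
  }
  # a cohort of one with lifespan 5: present for steps 0..4, gone at 5
  expect_equal(present, c(1, 1, 1, 1, 1, 0))
  expect_length(st$hsc$pos, 1)  # effectively unbounded lifespan: untouched
})
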