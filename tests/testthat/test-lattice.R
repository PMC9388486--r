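test_that("moore neighbourhood truncates at boundaries and is symmetric", {
  dims <- c(9L, 9L)
  expect_equal(nrow(moore_neighbors(c(5, 5), dims)), 8)
  expect_equal(nrow(moore_neighbors(c(1, 1), dims)), 3)
  expect_equal(nrow(moore_neighbors(c(1, 5), dims)), 5)
  # hand-enumerated edge (non-corner) neighbourhood
  expect_setequal(
    apply(moore_neighbors(c(1, 5), dims), 1, paste, collapse = ","),
    c("1,4", "1,6", "2,4", "2,5", "2,6"))
  expect_error(moore_neighbors(c(0, 5), dims), "out of bounds")

  # symmetry: q in N(p) <=> p in N(q), over every pair in a 6x7 lattice
  dims <- c(6L, 7L)
  key <- function(p) paste(p[1], p[2])
  nbs <- list()
  for (r in 1:6) for (c in 1:7) {
    nbs[[key(c(r, c))]] <- apply(moore_neighbors(c(r, c), dims), 1, paste,
                                 collapse = " ")
  }
  for (p in names(nbs)) for (q in nbs[[p]]) {
    expect_true(p %in% nbs[[q]])
  }
})

test_that("zonation equals a brute-force distance transform on a 21x21 lobule", {
  cfg <- tiny_config()
  st <- build_lobule(cfg)
  # oracle: min Euclidean distance over all 441 cells to the 9 vein sites
  vs <- st$vein_sites
  oracle <- matrix(NA_real_, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    oracle[i, j] <- min(sqrt((i - vs[, 1])^2 + (j - vs[, 2])^2))
  }
  expect_equal(st$zon, exp(-oracle / cfg$geometry$lambda))
  expect_equal(st$zon[11, 11], 1)
  corners <- c(st$zon[1, 1], st$zon[1, 21], st$zon[21, 1], st$zon[21, 21])
  expect_true(all(corners == min(st$zon)))
})

test_that("initial placement honours the configured cell ratios", {
  st <- build_lobule(sim_config(seed = 7))
  n_hep <- sum(st$occ == occupancy_codes()[["hepatocyte"]])
  placed <- n_hep + length(st$kc$pos) + length(st$hsc$pos)
  frac <- length(st$kc$pos) / placed
  # binomial-scale tolerance around the configured 15%
  expect_lt(abs(frac - 0.15), 0.01)
  expect_lt(abs(length(st$hsc$pos) / placed - 0.05), 0.01)

  st0 <- build_lobule(sim_config(hsc_ratio = 0, seed = 7))
  expect_length(st0$hsc$pos, 0)

  # portal fibroblasts only on the rings adjacent to portal tracts
  ring <- unlist(lapply(st$portal_blocks, function(blk) {
    rc <- cbind(((blk - 1L) %% st$nr) + 1L, ((blk - 1L) %/% st$nr) + 1L)
    unlist(lapply(seq_len(nrow(rc)), function(i) {
      nb <- moore_neighbors(rc[i, ], c(st$nr, st$nc))
      (nb[, 2] - 1L) * st$nr + nb[, 1]
    }))
  }))
  expect_true(all(st$pf$pos %in% ring))
})

test_that("configuration errors are rejected before any simulation", {
  expect_error(sim_config(kc_ratio = 0.7, hsc_ratio = 0.4),
               class = "lobulefib_config_error")
  expect_error(sim_config(width = 10, height = 10),
               class = "lobulefib_config_error")
  expect_error(sim_config(vein_centers = list(c(2L, 2L))),  # overlaps a tract
               class = "lobulefib_config_error")
  expect_error(sim_config(interval = 0), class = "lobulefib_config_error")
})

test_that("occupancy layer is exclusive; residents stack freely", {
  st <- build_lobule(tiny_config())
  blank <- c(11L, 14L)
  st <- remove_agent(st, blank)
  expect_true(is_vacant(st, blank))
  st <- place_agent(st, blank, "hepatocyte")
  expect_false(is_vacant(st, blank))
  expect_identical(occupant(st, blank), "hepatocyte")
  # second space-occupier on the same cell is a collision
  expect_error(place_agent(st, blank, "collagen_mfb"),
               class = "lobulefib_occupancy_error")
  # non-occupying agents may share the cell with the hepatocyte
  n0 <- length(st$mfb$pos)
  st <- place_agent(st, blank, "myofibroblast")
  expect_length(st$mfb$pos, n0 + 1)
  expect_identical(occupant(st, blank), "hepatocyte")
})

test_that("lobule construction is bit-reproducible under a fixed seed", {
  a <- build_lobule(sim_config(seed = 99))
  b <- build_lobule(sim_config(seed = 99))
  expect_identical(a$occ, b$occ)
  expect_identical(a$kc, b$kc)
  expect_identical(a$hsc, b$hsc)
})
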