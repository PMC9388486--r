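# Shared helpers for the test suite.  Fixtures are built in code; the heavier
# default-geometry runs are cached per test session.

# small lattice for pure-geometry tests
tiny_config <- function(...) {
  sim_config(width = 21L, height = 21L,
             vein_centers = list(c(11L, 11L)),
             portal_centers = list(c(2L, 2L), c(2L, 20L),
                                   c(20L, 2L), c(20L, 20L)),
             n_steps = 5L, seed = 42L, ...)
}

# independent naive double-loop implementation of the share-with-8-neighbours
# diffusion kernel, used as the oracle for the production kernel
diffuse_oracle <- function(v, p, torus = FALSE) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- out[i, j] + (1 - p) * v[i, j]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (torus) {
        ii <- ((ii - 1) %% nr) + 1; jj <- ((jj - 1) %% nc) + 1
        out[ii, jj] <- out[ii, jj] + p / 8 * v[i, j]
      } else if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        out[ii, jj] <- out[ii, jj] + p / 8 * v[i, j]
      }
    }
  }
  out
}

# deposit a value into a field matrix of a built state (test shim)
poke_field <- function(state, field, pos, value) {
  state$fields[[field]]$values[pos[1], pos[2]] <- value
  state
}

# linear index helper matching the state's column-major layout
lin_index <- function(state, pos) (pos[2] - 1L) * state$nr + pos[1]
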