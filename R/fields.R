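#' Diffusible mediator field
#'
#' A non-negative concentration lattice for one mediator (CCl4, HMGB1,
#' TNF-alpha or TGF-beta) together with its transport coefficients: the
#' share fraction redistributed to the eight Moore neighbours per step and
#' the first-order decay rate.
#'
#' @param name Field name.
#' @param nrow,ncol Lattice dimensions.
#' @param share Fraction in `[0, 1]` of each cell's value redistributed per
#'   diffusion step.
#' @param decay Fraction in `[0, 1)` removed per decay step.
#' @param values Optional initial concentration matrix (default all zero).
#' @return An object of class `diffusible_field`.
#' @export
new_field <- function(name, nrow, ncol, share, decay, values = NULL) {
  if (is.null(values)) values <- matrix(0, nrow, ncol)
  stopifnot(share >= 0, share <= 1, decay >= 0, decay < 1, all(values >= 0))
  structure(list(name = name, values = values, share = share, decay = decay),
            class = "diffusible_field")
}

#' @export
print.diffusible_field <- function(x, ...) {
  cat(sprintf("<diffusible_field> %s %d x %d, share %.3g, decay %.3g, total %.4g\n",
              x$name, nrow(x$values), ncol(x$values), x$share, x$decay,
              sum(x$values)))
  invisible(x)
}

# one synchronous share-with-8-neighbours diffusion step on a bare matrix.
# Each cell keeps (1 - p) v and sends p v / 8 towards each of its eight Moore
# neighbours; with absorbing boundaries the parts aimed off-lattice are lost,
# on a torus they wrap (mass-conserving test topology).
diffuse_values <- function(v, p, boundary = "absorbing") {
  if (p == 0) return(v)
  out <- (1 - p) * v
  s <- (p / 8) * v
  for (dr in -1:1) for (dc in -1:1) {
    if (dr != 0L || dc != 0L) out <- out + shift_matrix(s, dr, dc, boundary)
  }
  out
}

# contribution matrix shifted by (dr, dc): out[i, j] = m[i - dr, j - dc]
shift_matrix <- function(m, dr, dc, boundary = "absorbing") {
  nr <- nrow(m); nc <- ncol(m)
  if (boundary == "torus") {
    ri <- ((seq_len(nr) - 1L - dr) %% nr) + 1L
    ci <- ((seq_len(nc) - 1L - dc) %% nc) + 1L
    return(m[ri, ci, drop = FALSE])
  }
  out <- matrix(0, nr, nc)
  r_dst <- max(1L, 1L + dr):min(nr, nr + dr)
  c_dst <- max(1L, 1L + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

#' Field operations: diffusion, decay, deposit
#'
#' `diffuse()` performs one synchronous diffusion step in which every cell
#' retains `(1 - share)` of its value and sends `share / 8` of it towards each
#' of its eight Moore neighbours; shares aimed across the lattice edge are
#' lost (`boundary = "absorbing"`, the model's boundary condition) or wrap
#' around (`boundary = "torus"`, a mass-conserving topology used for
#' verification).  `decay_field()` multiplies every value by `(1 - decay)`.
#' `deposit()` adds `amount >= 0` at one position.
#'
#' @param field A `diffusible_field`.
#' @param boundary `"absorbing"` or `"torus"`.
#' @param pos `c(row, col)`, 1-based.
#' @param amount Non-negative quantity to add.
#' @return The updated field.
#' @examples
#' f <- new_field("tnf", 5, 5, share = 0.4, decay = 0.1)
#' f <- deposit(f, c(3, 3), 1)
#' f <- diffuse(f)
#' f$values[3, 3]          # 0.6
#' f$values[2, 2]          # 0.05
#' @export
diffuse <- function(field, boundary = c("absorbing", "torus")) {
  boundary <- match.arg(boundary)
  field$values <- diffuse_values(field$values, field$share, boundary)
  field
}

#' @rdname diffuse
#' @export
decay_field <- function(field) {
  field$values <- field$values * (1 - field$decay)
  field
}

#' @rdname diffuse
#' @export
deposit <- function(field, pos, amount) {
  if (amount < 0) stop("deposit amount must be non-negative")
  field$values[pos[1], pos[2]] <- field$values[pos[1], pos[2]] + amount
  field
}

#' @rdname diffuse
#' @export
field_total <- function(field) sum(field$values)
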