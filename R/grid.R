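#' Periodic finite-volume grid
#'
#' Constructs a flat, periodic 2-D finite-volume mesh with square cells.
#' Cell centers sit at `(m + 1/2) * dx` (0-based cell indices); faces are
#' indexed by the cell on their negative side, so the face `x`-array entry
#' `[i, j]` is the face between cells `(i, j)` and `(i + 1, j)` (with
#' periodic wrap).  Scalar fields on the grid ("cell fields") are plain
#' `nx` x `ny` numeric matrices with the x index varying fastest, matching
#' R's column-major storage.
#'
#' @param nx,ny integer number of cells per axis (at least 4).
#' @param dx cell width, common to both axes (square cells).
#' @return An object of class `selm_grid`: a list with `nx`, `ny`, `dx`,
#'   domain lengths `Lx`, `Ly`, cell volume `dV`, and cell-center
#'   coordinate vectors `xc`, `yc`.
#' @examples
#' g <- selm_grid(20, 20, 0.1)
#' g$Lx
#' @export
selm_grid <- function(nx, ny = nx, dx = 1 / nx) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 4L || ny < 4L) stop("grid must have at least 4 cells per axis")
  if (!is.finite(dx) || dx <= 0) stop("dx must be positive and finite")
  g <- list(
    nx = nx, ny = ny, dx = dx,
    Lx = nx * dx, Ly = ny * dx,
    dV = dx^2,
    xc = (seq_len(nx) - 0.5) * dx,
    yc = (seq_len(ny) - 0.5) * dx
  )
  class(g) <- "selm_grid"
  g
}

#' @export
print.selm_grid <- function(x, ...) {
  cat(sprintf("<selm_grid> %d x %d cells, dx = %g, domain %g x %g\n",
              x$nx, x$ny, x$dx, x$Lx, x$Ly))
  invisible(x)
}

#' Cell field constructor
#'
#' @param grid a [selm_grid()].
#' @param values scalar or `nx*ny` vector/matrix of cell values.
#' @return `nx` x `ny` numeric matrix.
#' @export
cell_field <- function(grid, values = 0) {
  m <- matrix(values, grid$nx, grid$ny)
  if (!all(is.finite(m))) stop("cell field values must be finite")
  m
}

#' Face field constructor
#'
#' A face field holds one scalar per cell face per axis, stored as two
#' `nx` x `ny` matrices (`x`, `y`), each face indexed by the cell on its
#' negative side.
#'
#' @param grid a [selm_grid()].
#' @param x,y scalars or matrices of face values for the two axes.
#' @export
face_field <- function(grid, x = 0, y = 0) {
  f <- list(x = matrix(x, grid$nx, grid$ny), y = matrix(y, grid$nx, grid$ny))
  class(f) <- "selm_face_field"
  f
}

# periodic shifts of a cell matrix: shift_px(F)[i,j] = F[i+1,j], etc.
shift_px <- function(m) m[c(seq_len(nrow(m))[-1L], 1L), , drop = FALSE]
shift_mx <- function(m) m[c(nrow(m), seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_py <- function(m) m[, c(seq_len(ncol(m))[-1L], 1L), drop = FALSE]
shift_my <- function(m) m[, c(ncol(m), seq_len(ncol(m) - 1L)), drop = FALSE]

#' Discrete gradient (cells to faces)
#'
#' Central-difference gradient of a cell field, returning a face field:
#' `(F(x_m + e_d) - F(x_m)) / dx` at face `x_m + (1/2) e_d`, with periodic
#' wrap.  The operator is linear and is the negative adjoint of
#' [fv_divergence()] under the unweighted Euclidean pairing.
#'
#' @param f cell field (matrix) on `grid`.
#' @param grid a [selm_grid()].
#' @return A `selm_face_field`.
#' @export
fv_gradient <- function(f, grid) {
  if (!all(is.finite(f))) stop("fv_gradient: non-finite input values")
  out <- list(x = (shift_px(f) - f) / grid$dx,
              y = (shift_py(f) - f) / grid$dx)
  class(out) <- "selm_face_field"
  out
}

#' Discrete divergence (faces to cells)
#'
#' `div(J)(x_m) = (1/dx) * sum_d [J_d(x_m + e_d/2) - J_d(x_m - e_d/2)]`
#' with periodic wrap.  Telescopes to zero when summed over the grid, so any
#' flux-form update conserves the cell sum to machine precision.
#'
#' @param J face field on `grid`.
#' @param grid a [selm_grid()].
#' @return Cell field (matrix).
#' @export
fv_divergence <- function(J, grid) {
  if (!all(is.finite(J$x)) || !all(is.finite(J$y)))
    stop("fv_divergence: non-finite input values")
  (J$x - shift_mx(J$x) + J$y - shift_my(J$y)) / grid$dx
}

#' Average cell values onto faces
#'
#' Arithmetic mean of the two cells adjacent to each face; used for the
#' face-centered transport coefficients (diffusivity, q, temperature).
#'
#' @inheritParams fv_gradient
#' @export
cells_to_faces <- function(f, grid) {
  out <- list(x = (f + shift_px(f)) / 2, y = (f + shift_py(f)) / 2)
  class(out) <- "selm_face_field"
  out
}

#' Average face values back onto cells
#'
#' Each cell receives the mean of its two adjacent faces on each axis,
#' summed over axes.  Summing the result over cells equals summing the face
#' values over faces, so face-localized heating deposited this way is
#' conserved exactly.
#'
#' @param J face field on `grid`.
#' @inheritParams fv_gradient
#' @export
faces_to_cells <- function(J, grid) {
  (J$x + shift_mx(J$x) + J$y + shift_my(J$y)) / 2
}

#' Dense matrix forms of the discrete operators
#'
#' Builds the dense divergence matrix `D` (cells x faces) and gradient
#' matrix `G` (faces x cells) for a small grid, with faces stacked as
#' (all x-faces, all y-faces) in column-major cell order.  These satisfy
#' `G = -t(D)` exactly and serve as oracles for the operator routines and
#' the dissipative-block constructions.
#'
#' @param grid a [selm_grid()].
#' @return For [fv_divergence_matrix()], an `N x 2N` matrix (`N = nx*ny`);
#'   for [fv_gradient_matrix()], its `2N x N` negative transpose built
#'   independently from the stencil.
#' @export
fv_divergence_matrix <- function(grid) {
  N <- grid$nx * grid$ny
  D <- matrix(0, N, 2L * N)
  for (k in seq_len(2L * N)) {
    J <- face_field(grid)
    if (k <= N) J$x[k] <- 1 else J$y[k - N] <- 1
    D[, k] <- as.vector(fv_divergence(J, grid))
  }
  D
}

#' @rdname fv_divergence_matrix
#' @export
fv_gradient_matrix <- function(grid) {
  N <- grid$nx * grid$ny
  G <- matrix(0, 2L * N, N)
  for (k in seq_len(N)) {
    f <- cell_field(grid)
    f[k] <- 1
    g <- fv_gradient(f, grid)
    G[, k] <- c(as.vector(g$x), as.vector(g$y))
  }
  G
}

#' Minimum-image displacement on the periodic domain
#'
#' @param d displacement (vector or matrix of components).
#' @param L domain length for the axis.
#' @return Displacement wrapped to `[-L/2, L/2)`.
#' @export
min_image <- function(d, L) d - L * round(d / L)

# wrap a coordinate into [0, L)
wrap_coord <- function(x, L) x - L * floor(x / L)
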