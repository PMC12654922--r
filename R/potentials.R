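#' Potentials acting on the protein and the species
#'
#' A potential object supplies the protein potential energy `Psi(X)` with
#' its gradient, and (optionally) the species chemical potential
#' `Phi(x; X)` per cell together with its `X`-gradient.  Concrete variants:
#'
#' * [potential_none()]: `Psi = Phi = 0`.
#' * [potential_harmonic()]: `Psi = (k/2) |X - a|^2` (minimum-image), no `Phi`.
#' * [potential_kernel_coupling()]: `Phi(x; X) = s * eta(x - X)` with the
#'   truncated-Gaussian kernel `eta` (amplitude `k1`).  The default sign
#'   `s = -1` makes the interaction attractive: the force on the protein
#'   points toward higher interpolated concentration, and the species
#'   drifts down `Phi` toward the protein.  The literal repulsive sign is
#'   available via `sign = +1`.
#' * [potential_well_lattice()]: `Psi(X) = sum_i -c2 exp(-|X - X_i|^2 /
#'   (2 sigma0^2))`, Gaussian energy wells on a lattice of centers, no `Phi`.
#'
#' All gradients are analytic and match finite differences of the values.
#'
#' @name potentials
NULL

#' @rdname potentials
#' @export
potential_none <- function() {
  p <- list(kind = "none",
            psi = function(X, grid = NULL) list(value = 0, grad = c(0, 0)),
            has_phi = FALSE)
  class(p) <- "selm_potential"
  p
}

#' @rdname potentials
#' @param k spring constant.
#' @param center well center `a` (length-2).
#' @export
potential_harmonic <- function(k, center = c(0, 0)) {
  force(k); force(center)
  p <- list(kind = "harmonic", k = k, center = center,
            psi = function(X, grid = NULL) {
              d <- X - center
              if (!is.null(grid)) d <- c(min_image(d[1], grid$Lx),
                                         min_image(d[2], grid$Ly))
              list(value = k / 2 * sum(d^2), grad = k * d)
            },
            has_phi = FALSE)
  class(p) <- "selm_potential"
  p
}

#' @rdname potentials
#' @param k1 coupling amplitude of the interaction kernel.
#' @param sigma0 kernel width.
#' @param sign overall sign `s` of the coupling (`-1` attractive, default).
#' @param r_cut kernel truncation radius (default `4 * sigma0`).
#' @export
potential_kernel_coupling <- function(k1 = 1.1, sigma0 = 0.2, sign = -1,
                                      r_cut = 4 * sigma0) {
  kern <- kernel_spec("gaussian", sigma0 = sigma0, k1 = k1, r_cut = r_cut)
  p <- list(kind = "kernel", kernel = kern, sign = sign,
            psi = function(X, grid = NULL) list(value = 0, grad = c(0, 0)),
            has_phi = TRUE,
            # Phi(x_m; X) = s * eta(x_m - X)
            phi_cells = function(grid, X)
              sign * kernel_on_grid(X, kern, grid),
            # grad_X Phi = -s * grad_x eta(x_m - X) = s * ((x_m - X)/sigma0^2) eta
            phi_gradX = function(grid, X) {
              g <- spread_kernel_gradient(X, kern, grid)
              list(x = -sign * g$x, y = -sign * g$y)
            })
  class(p) <- "selm_potential"
  p
}

#' @rdname potentials
#' @param c2 well strength (energy units).
#' @param centers matrix of well centers (rows are `(x, y)` positions).
#' @export
potential_well_lattice <- function(c2, sigma0 = 0.2, centers) {
  centers <- matrix(centers, ncol = 2)
  p <- list(kind = "wells", c2 = c2, sigma0 = sigma0, centers = centers,
            psi = function(X, grid = NULL) {
              dx <- X[1] - centers[, 1]; dy <- X[2] - centers[, 2]
              if (!is.null(grid)) {
                dx <- min_image(dx, grid$Lx); dy <- min_image(dy, grid$Ly)
              }
              e <- exp(-(dx^2 + dy^2) / (2 * sigma0^2))
              list(value = -c2 * sum(e),
                   grad = c(sum(c2 * dx / sigma0^2 * e),
                            sum(c2 * dy / sigma0^2 * e)))
            },
            has_phi = FALSE)
  class(p) <- "selm_potential"
  p
}

#' Staggered lattice of well centers
#'
#' Rows spaced `spacing` apart in `y`, alternate rows offset by half a
#' spacing in `x` (hexagonal-like arrangement), commensurate with the
#' periodic domain.  With the default 2 x 2 domain and `spacing = 2/3` the
#' lattice contains the escape-study well center `(5/3, 1)`.
#'
#' @param Lx,Ly domain lengths.
#' @param spacing lattice spacing (must divide `Lx` and `Ly`).
#' @return Matrix of center coordinates (one row per well).
#' @export
well_lattice_centers <- function(Lx = 2, Ly = 2, spacing = 2 / 3) {
  nxw <- round(Lx / spacing); nyw <- round(Ly / spacing)
  if (abs(nxw * spacing - Lx) > 1e-9 || abs(nyw * spacing - Ly) > 1e-9)
    stop("spacing must divide the domain lengths")
  out <- NULL
  for (j in seq_len(nyw) - 1L) {
    y <- (j + 0.5) * spacing
    off <- if (j %% 2 == 1) 0.5 * spacing else 0
    x <- (seq_len(nxw) - 1L) * spacing + off
    out <- rbind(out, cbind(x, y))
  }
  dimnames(out) <- NULL
  out
}
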