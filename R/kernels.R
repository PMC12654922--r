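#' Radial coupling kernels
#'
#' Truncated-Gaussian (default) and Peskin-delta radial kernels used for the
#' particle--field coupling: the interaction kernel `eta` with amplitude
#' `k1`, and the unit-amplitude sensing/interface kernel `zeta` (`k1 = 1`).
#' In two dimensions the Gaussian normalization is `Z = 2*pi*sigma0^2`, so
#' `eta(0) = k1 / (2*pi*sigma0^2)` and the unit kernel integrates to 1 up to
#' a truncation defect below 1e-3 at the default cutoff `r_cut = 4*sigma0`
#' (missing mass `exp(-8)`).  Weights beyond `r_cut` are zero and are not
#' renormalized.
#'
#' @param kind `"gaussian"` or `"peskin_delta"`.
#' @param sigma0 kernel width (length units); for the Peskin kernel this is
#'   interpreted as the mesh width `h` of the standard 4-point kernel.
#' @param k1 amplitude (dimensionless coupling strength; 1 for sensing).
#' @param r_cut truncation radius; defaults to `4*sigma0` (Gaussian) or
#'   `2*sigma0` (Peskin support).
#' @return An object of class `selm_kernel`.
#' @export
kernel_spec <- function(kind = c("gaussian", "peskin_delta"),
                        sigma0, k1 = 1, r_cut = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(sigma0) || sigma0 <= 0) stop("sigma0 must be positive")
  if (is.null(r_cut)) r_cut <- if (kind == "gaussian") 4 * sigma0 else 2 * sigma0
  if (kind == "gaussian" && r_cut < 3 * sigma0)
    stop("gaussian kernel requires r_cut >= 3*sigma0")
  k <- list(kind = kind, sigma0 = sigma0, k1 = k1, r_cut = r_cut,
            Z = 2 * pi * sigma0^2)
  class(k) <- "selm_kernel"
  k
}

# 1-D Peskin 4-point kernel on mesh width h (support |r| < 2h)
peskin_phi <- function(r, h) {
  a <- abs(r) / h
  w <- numeric(length(a))
  i1 <- a < 1
  i2 <- !i1 & a < 2
  w[i1] <- (3 - 2 * a[i1] + sqrt(1 + 4 * a[i1] - 4 * a[i1]^2)) / 8
  w[i2] <- (5 - 2 * a[i2] - sqrt(-7 + 12 * a[i2] - 4 * a[i2]^2)) / 8
  w / h
}

#' Evaluate a radial kernel at displacements
#'
#' @param kernel a [kernel_spec()].
#' @param sx,sy displacement components (already minimum-imaged by callers
#'   working on the periodic domain).
#' @return Kernel weight(s); zero beyond the truncation radius.
#' @export
kernel_eval <- function(kernel, sx, sy = 0) {
  if (!all(is.finite(sx)) || !all(is.finite(sy)))
    stop("kernel_eval: non-finite displacement")
  r2 <- sx^2 + sy^2
  if (kernel$kind == "gaussian") {
    w <- kernel$k1 / kernel$Z * exp(-r2 / (2 * kernel$sigma0^2))
    w * (r2 <= kernel$r_cut^2)
  } else {
    kernel$k1 * peskin_phi(sx, kernel$sigma0) * peskin_phi(sy, kernel$sigma0)
  }
}

#' Analytic spatial gradient of a Gaussian kernel
#'
#' Returns `grad_x eta(s) = -(s / sigma0^2) * eta(s)` componentwise.
#'
#' @inheritParams kernel_eval
#' @return List with components `x` and `y`.
#' @export
kernel_gradient <- function(kernel, sx, sy = 0) {
  if (kernel$kind != "gaussian")
    stop("analytic gradient implemented for the gaussian kernel")
  w <- kernel_eval(kernel, sx, sy)
  list(x = -sx / kernel$sigma0^2 * w, y = -sy / kernel$sigma0^2 * w)
}

# minimum-image displacements from every cell center to X: list(sx, sy) matrices
cell_displacements <- function(grid, X) {
  sx <- min_image(outer(grid$xc - X[1], rep(1, grid$ny)), grid$Lx)
  sy <- min_image(outer(rep(1, grid$nx), grid$yc - X[2]), grid$Ly)
  list(sx = sx, sy = sy)
}

check_kernel_domain <- function(kernel, grid) {
  if (kernel$r_cut > min(grid$Lx, grid$Ly) / 2)
    stop("kernel support exceeds half the periodic domain (self-overlap)")
}

#' Sample a kernel on the grid around a particle
#'
#' Evaluates `eta(x_m - X)` at every cell center with the minimum-image
#' convention.
#'
#' @param X particle position (length-2).
#' @param kernel a [kernel_spec()].
#' @param grid a [selm_grid()].
#' @return Cell field of kernel weights.
#' @export
kernel_on_grid <- function(X, kernel, grid) {
  check_kernel_domain(kernel, grid)
  s <- cell_displacements(grid, X)
  kernel_eval(kernel, s$sx, s$sy)
}

#' Interpolate a cell field at a particle position
#'
#' Kernel-weighted quadrature `sum_m eta(x_m - X) f(x_m) dV`, smooth in `X`.
#' With the unit-amplitude kernel this approximates the continuum integral
#' `int zeta(x - X) f(x) dx` to second order in the mesh width.
#'
#' @param f cell field (matrix) on `grid`.
#' @inheritParams kernel_on_grid
#' @return Scalar.
#' @export
interpolate_field <- function(f, X, kernel, grid) {
  sum(kernel_on_grid(X, kernel, grid) * f) * grid$dV
}

#' Kernel spatial gradient spread over the grid
#'
#' Returns the analytic kernel gradient `grad_x eta(x_m - X)` sampled at
#' every cell (both components), used to assemble the concentration-coupled
#' force on the protein.
#'
#' @inheritParams kernel_on_grid
#' @return List of two cell fields, `x` and `y`.
#' @export
spread_kernel_gradient <- function(X, kernel, grid) {
  check_kernel_domain(kernel, grid)
  s <- cell_displacements(grid, X)
  kernel_gradient(kernel, s$sx, s$sy)
}
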