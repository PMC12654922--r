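#' Array of thermal sensor proteins
#'
#' Fixed sensing sites (e.g. TRP-like channel positions) that read the
#' membrane temperature field through the unit-amplitude Gaussian kernel
#' `zeta` of width `sigma0`, and low-pass filter the sensed temperature
#' through a first-order (exponential) response with rate `lambda` and DC
#' gain `beta0`.
#'
#' @param grid a [selm_grid()].
#' @param positions matrix of sensor positions (rows `(x, y)`); default one
#'   sensor per cell column along the mid-height line.
#' @param sigma0 sensing kernel width.
#' @param lambda filter rate of the exponential response `lambda *
#'   exp(-lambda * tau)`.
#' @param beta0 filter gain; at steady uniform temperature `theta` the
#'   filtered signal equilibrates to `beta0 * theta`.
#' @return Object of class `selm_sensors`; precomputes the quadrature
#'   weight matrix so repeated sensing is a matrix product.
#' @export
sensor_array <- function(grid, positions = NULL, sigma0 = 0.1,
                         lambda = 1e4, beta0 = 1 / 3) {
  if (is.null(positions))
    positions <- cbind(grid$xc, grid$Ly / 2)
  positions <- matrix(positions, ncol = 2)
  zeta <- kernel_spec("gaussian", sigma0 = sigma0, k1 = 1)
  W <- t(vapply(seq_len(nrow(positions)), function(i)
    as.vector(kernel_on_grid(positions[i, ], zeta, grid)) * grid$dV,
    numeric(grid$nx * grid$ny)))
  s <- list(positions = positions, kernel = zeta, lambda = lambda,
            beta0 = beta0, W = W, grid = grid)
  class(s) <- "selm_sensors"
  s
}

#' Kernel-sensed temperature at each sensor
#'
#' `Qbar(x_i) = sum_m zeta(x_m - x_i) thetaC(x_m) dV`, the kernel-weighted
#' local average of the membrane temperature at each sensor site.
#'
#' @param thetaC membrane temperature cell field (matrix, or a matrix of
#'   flattened snapshots with one column per time).
#' @param sensors a [sensor_array()].
#' @return Vector of sensed temperatures (or matrix, sensors x times).
#' @export
sensed_temperature <- function(thetaC, sensors) {
  out <- sensors$W %*% (if (is.matrix(thetaC) &&
                            nrow(thetaC) == ncol(sensors$W))
                          thetaC else as.vector(thetaC))
  if (ncol(out) == 1) drop(out) else out
}

#' Update the filtered sensor signal
#'
#' Exact exponential-integrator discretization of the convolution with the
#' response `lambda * exp(-lambda * tau)`:
#' `Ibar_now = exp(-lambda dt) Ibar_prev + (1 - exp(-lambda dt)) beta0
#' Qbar_now`.  Unconditionally stable; the fixed point under constant
#' input is `beta0 * Qbar` (unit DC gain times `beta0`), and in the
#' `lambda * dt -> Inf` limit the filter tracks `beta0 * Qbar`
#' instantaneously.
#'
#' @param Ibar_prev previous filtered value(s).
#' @param Qbar_now current sensed temperature(s).
#' @param dt time step.
#' @param lambda filter rate (must be nonnegative).
#' @param beta0 filter gain.
#' @export
update_filtered_signal <- function(Ibar_prev, Qbar_now, dt, lambda, beta0) {
  if (lambda < 0) stop("lambda must be nonnegative")
  w <- exp(-lambda * dt)
  w * Ibar_prev + (1 - w) * beta0 * Qbar_now
}
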