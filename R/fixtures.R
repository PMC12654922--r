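#' Programmatic field and state fixtures
#'
#' Seeded constructors for the initial conditions used by the simulation
#' studies and for small states used in operator-level verification.
#'
#' @name fixtures
NULL

#' @describeIn fixtures Periodic (minimum-image) Gaussian blob, normalized
#'   so that `sum(q) * dV = 1` (a unit-mass distribution).
#' @param grid a [selm_grid()].
#' @param center blob center.
#' @param sigma blob width.
#' @param normalize `"mass"` (unit integral) or `"none"` (unit peak).
#' @export
gaussian_blob_field <- function(grid, center, sigma, normalize = "mass") {
  s <- cell_displacements(grid, center)
  f <- exp(-(s$sx^2 + s$sy^2) / (2 * sigma^2))
  if (normalize == "mass") f <- f / (sum(f) * grid$dV)
  f
}

#' @describeIn fixtures Sinusoidal temperature profile
#'   `theta0 * (1 + a0 * sin(pi * (k . x) / L))` with `L` the domain width.
#' @param theta0 baseline temperature.
#' @param a0 modulation amplitude.
#' @param kvec integer wave vector, default `c(1, 0)`.
#' @export
sinusoid_temperature <- function(grid, theta0, a0, kvec = c(1, 0)) {
  ph <- pi * (outer(kvec[1] * grid$xc, rep(1, grid$ny)) +
              outer(rep(1, grid$nx), kvec[2] * grid$yc)) / grid$Lx
  theta0 * (1 + a0 * sin(ph))
}

#' @describeIn fixtures Localized heating profile
#'   `theta0 * (1 + c3 * exp(-|x - x0|^2 / (2 sigma3^2)))` (minimum-image).
#' @param c3 heating strength.
#' @param sigma3 heating spot width.
#' @export
heating_profile <- function(grid, theta0, c3, center, sigma3 = 0.3) {
  s <- cell_displacements(grid, center)
  theta0 * (1 + c3 * exp(-(s$sx^2 + s$sy^2) / (2 * sigma3^2)))
}

#' @describeIn fixtures Band-limited random smooth field: mean `mu` plus
#'   random low-order Fourier modes up to `kmax`, scaled to amplitude `amp`.
#' @param kmax highest mode retained per axis.
#' @param amp peak-to-peak amplitude scale.
#' @param mu mean value.
#' @export
bandlimited_field <- function(grid, kmax = 2, amp = 0.1, mu = 1) {
  f <- matrix(0, grid$nx, grid$ny)
  for (kx in 0:kmax) for (ky in 0:kmax) {
    if (kx == 0 && ky == 0) next
    ph <- 2 * pi * (kx * outer(grid$xc, rep(1, grid$ny)) +
                    ky * outer(rep(1, grid$nx), grid$yc)) / grid$Lx
    f <- f + stats::rnorm(1) * sin(ph) + stats::rnorm(1) * cos(ph)
  }
  if (max(abs(f)) > 0) f <- f / max(abs(f))
  mu + amp * f
}

#' @describeIn fixtures A small fully-populated state on a 4 x 4 grid with
#'   smooth non-uniform fields, for dense-operator verification.
#' @param seed RNG seed used for the random smooth fields.
#' @export
demo_state_4x4 <- function(seed = 1) {
  g <- selm_grid(4, 4, 0.5)
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    q <- bandlimited_field(g, kmax = 1, amp = 0.3, mu = 1)
    thC <- bandlimited_field(g, kmax = 1, amp = 0.25, mu = 3)
  })
  list(grid = g,
       state = selm_state(g, X = c(0.9, 1.1), q = q,
                          thetaP = 3.2, thetaI = 2.8, thetaC = thC))
}
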