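#' Physical parameters of the membrane-protein system
#'
#' Bundles the rate, capacity and transport constants of the model.  All
#' quantities are non-dimensional (see [nondimensional_report()] for the
#' reference scales).  The species drag `gamma` is tied to the tabulated
#' diffusivity through the Stokes-Einstein relation `kappa_bar = thetaC /
#' gamma`, enforced at the baseline temperature: `gamma = theta0 /
#' kappa_bar`.  The running diffusivity used by the dynamics is the local
#' `thetaC / gamma`, which equals `kappa_bar` at `theta0`.
#'
#' @param kB Boltzmann constant (energy/temperature).
#' @param c0 total concentration of the chemical species.
#' @param kappa_bar species diffusivity at the baseline temperature.
#' @param gamma_p particle (protein) drag; mobility is `I / gamma_p`.
#' @param kappaPI,kappaCI,kappaCC,kappa0 thermal conductivities:
#'   particle-interface, interface-membrane, membrane-membrane, and
#'   membrane-ambient.  `kappaCI` and `kappa0` may be zero.
#' @param C_P,C_C,C_I specific heats of the protein, the membrane field
#'   (per volume), and the interfacial region.
#' @param theta0 baseline temperature.
#' @return Object of class `selm_params`.
#' @export
selm_params <- function(kB = 1e-5, c0 = 2.1, kappa_bar = 1.2e-3,
                        gamma_p = 13, kappaPI = 8.2e6, kappaCI = 3.0e3,
                        kappaCC = 1.3e2, kappa0 = 2.1e-3,
                        C_P = 1.2, C_C = 1.3e2, C_I = 1.4e2, theta0 = 3.0) {
  p <- list(kB = kB, c0 = c0, kappa_bar = kappa_bar, gamma_p = gamma_p,
            kappaPI = kappaPI, kappaCI = kappaCI, kappaCC = kappaCC,
            kappa0 = kappa0, C_P = C_P, C_C = C_C, C_I = C_I,
            theta0 = theta0, gamma = theta0 / kappa_bar)
  for (nm in c("c0", "kappa_bar", "gamma_p", "kappaPI", "kappaCC",
               "C_P", "C_C", "C_I", "theta0"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("parameter %s must be strictly positive", nm))
  for (nm in c("kB", "kappaCI", "kappa0"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("parameter %s must be nonnegative", nm))
  class(p) <- "selm_params"
  p
}

#' @export
print.selm_params <- function(x, ...) {
  cat("<selm_params>\n")
  v <- unlist(x[setdiff(names(x), "gamma")])
  print(v)
  cat(sprintf("(derived species drag gamma = theta0/kappa_bar = %g)\n", x$gamma))
  invisible(x)
}

#' Parameter presets for the three simulation studies
#'
#' Returns the tabulated non-dimensional parameter set of one of the three
#' studies: `"table1"` (protein positioning in a concentration gradient),
#' `"table2"` (thermal gradient sensing), `"table3"` (hot Brownian escape
#' from energy wells).  The `"table2"` and `"table3"` tables do not list a
#' species diffusivity (the concentration field is inactive there); the
#' table-1 value is carried so `gamma` stays defined.
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return A `selm_params` object with attributes `grid` (nx, ny, dx) and
#'   `dt` (tabulated time step), plus study-specific extras (`k1`, `sigma0`,
#'   `c2`, `X0`, ...) as attribute `study`.
#' @export
selm_preset <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  p <- switch(name,
    table1 = selm_params(kB = 1e-5, c0 = 2.1, kappa_bar = 1.2e-3,
                         gamma_p = 13, kappaPI = 8.2e6, kappaCI = 3.0e3,
                         kappaCC = 1.3e2, kappa0 = 2.1e-3,
                         C_P = 1.2, C_C = 1.3e2, C_I = 1.4e2, theta0 = 3.0),
    table2 = selm_params(kB = 1e-3, c0 = 2.1, kappa_bar = 1.2e-3,
                         gamma_p = 13, kappaPI = 8.2e6, kappaCI = 0,
                         kappaCC = 8.2e4, kappa0 = 8.2e4,
                         C_P = 1.0, C_C = 4.0e1, C_I = 1.4e2, theta0 = 3.0),
    table3 = selm_params(kB = 1e-5, c0 = 2.1, kappa_bar = 1.2e-3,
                         gamma_p = 1.0e-1, kappaPI = 5.7e2, kappaCI = 3.0e3,
                         kappaCC = 2.1e-3, kappa0 = 8.2e6,
                         C_P = 9.3e2, C_C = 1.3e4, C_I = 1.4e2, theta0 = 3.0))
  attr(p, "grid") <- list(nx = 20L, ny = 20L, dx = 0.1)
  attr(p, "dt") <- switch(name, table1 = 1e-3, table2 = 1e-5, table3 = 3e-3)
  attr(p, "study") <- switch(name,
    table1 = list(k1 = 1.1, sigma0 = 0.2, x0 = c(0, 0), x1 = c(1.5, 1.5),
                  blob_sigma = 0.2),
    table2 = list(sigma0_sensor = 0.1, lambda = 1e4, beta0 = 1 / 3,
                  a0 = 1.0, kvec = c(1, 0)),
    table3 = list(c2 = 1.5e-4, sigma0 = 0.2, X0 = c(5 / 3, 1.0),
                  sigma3 = 0.3, r0 = 0.4))
  attr(p, "preset") <- name
  p
}
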