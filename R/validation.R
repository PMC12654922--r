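#' Spatial convergence of the conduction transfer operator
#'
#' Evolves the deterministic conduction part of the membrane temperature
#' equation (`d thetaC / dt = div(kappa grad thetaC) / C_C`) from a
#' single-mode sinusoidal initial condition on a sequence of dyadically
#' refined periodic grids, compares at time `T` against the exact
#' exponentially decaying sinusoid of the continuum equation, and fits the
#' log-log slope of the maximum-norm error against the mesh spacing.
#' Second-order spatial accuracy gives a slope near 2.
#'
#' The time step is tied to the mesh (`dt ~ dx^2`), well inside the
#' explicit stability bound, so the temporal error (second order in `dt`,
#' hence fourth order in `dx` here) is negligible against the spatial
#' error being measured.
#'
#' @param resolutions grid sizes (cells per axis), at least 3.
#' @param kappa conduction coefficient.
#' @param C_C heat capacity per volume.
#' @param T_end comparison time.
#' @param L domain length.
#' @param kvec integer mode, default `c(1, 0)`.
#' @param theta0,amplitude offset and amplitude of the initial sinusoid
#'   (offset keeps the field positive).
#' @param dt_safety fraction of the explicit diffusive stability limit
#'   used for the step.
#' @return Object of class `selm_convergence_report`: data frame of
#'   `(n, dx, error)`, the fitted `slope`, and a `pass` flag
#'   (slope within `[1.85, 2.15]` and errors strictly decreasing).
#' @export
transfer_operator_convergence <- function(resolutions = c(16, 32, 64),
                                          kappa = 1, C_C = 1, T_end = 0.02,
                                          L = 1, kvec = c(1, 0),
                                          theta0 = 2, amplitude = 0.5,
                                          dt_safety = 0.05) {
  stopifnot(length(resolutions) >= 3)
  Dth <- kappa / C_C
  lam <- Dth * sum((2 * pi * kvec / L)^2)
  rows <- lapply(resolutions, function(n) {
    g <- selm_grid(n, n, L / n)
    ph <- 2 * pi * (kvec[1] * outer(g$xc, rep(1, n)) +
                    kvec[2] * outer(rep(1, n), g$yc)) / L
    u0 <- theta0 + amplitude * sin(ph)
    p <- selm_params(kB = 0, kappaCC = kappa, C_C = C_C, kappa0 = 0,
                     kappaCI = 0, theta0 = theta0)
    m <- selm_model(g, p, potential_none(), active = "thetaC")
    dt_stab <- g$dx^2 / (8 * Dth)
    n_steps <- ceiling(T_end / (dt_safety * dt_stab))
    dt <- T_end / n_steps
    tr <- run_selm(selm_state(g, thetaC = u0), m, dt, n_steps, noise = FALSE)
    exact <- theta0 + amplitude * exp(-lam * T_end) * sin(ph)
    data.frame(n = n, dx = g$dx,
               error = max(abs(tr$final$thetaC - exact)))
  })
  tab <- do.call(rbind, rows)
  if (any(diff(tab$error) >= 0))
    warning("errors do not decrease monotonically under refinement")
  slope <- unname(stats::coef(stats::lm(log(error) ~ log(dx), tab))[2])
  rep <- list(table = tab, slope = slope,
              pass = slope > 1.85 && slope < 2.15 && all(diff(tab$error) < 0))
  class(rep) <- "selm_convergence_report"
  rep
}

#' @export
print.selm_convergence_report <- function(x, ...) {
  cat("<conduction transfer-operator convergence>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("observed order: %.3f  [%s]\n", x$slope,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Reference frozen problem for fluctuation checks
#'
#' A fully-populated 4 x 4 state with smooth non-uniform fields and a
#' gentle, explicitly-stable parameter set in which every dissipative
#' block (protein, species, conduction, the two exchanges, ambient) is
#' active.  Used by the increment-covariance test and the factorization
#' checks.
#'
#' @param seed seed for the random smooth fields.
#' @return List with `state` and `model`.
#' @export
validation_reference_problem <- function(seed = 1) {
  fx <- demo_state_4x4(seed)
  p <- selm_params(kB = 1e-3, c0 = 1.5, kappa_bar = 0.02, gamma_p = 2,
                   kappaPI = 5, kappaCI = 2, kappaCC = 0.5, kappa0 = 0.3,
                   C_P = 1.2, C_C = 2, C_I = 1.5, theta0 = 3)
  pot <- potential_kernel_coupling(k1 = 0.8, sigma0 = 0.3, r_cut = 0.9)
  m <- selm_model(fx$grid, p, pot,
                  interface_kernel = kernel_spec("gaussian", sigma0 = 0.3,
                                                 r_cut = 0.9))
  list(state = fx$state, model = m)
}

#' Covariance of integrator increments vs the dissipative target
#'
#' Freezes a state, draws `n` independent single steps of the two-stage
#' integrator from it, and compares the empirical covariance of the state
#' increments entrywise against the fluctuation-dissipation target
#' `2 kB K(Y) dt`, where `K` is the dense assembled dissipative operator.
#' Entrywise z-scores use the Gaussian sampling error of a covariance
#' estimate, `se = sqrt((K_ii K_jj + K_ij^2)) * (2 kB dt) / sqrt(n)`.
#'
#' @param state frozen [selm_state()] (small grid).
#' @param model the [selm_model()].
#' @param dt step size (small, so the state-dependence of the noise
#'   amplitude across the step is negligible).
#' @param n number of sampled steps.
#' @param z_limit failure threshold on `|z|`.
#' @return Object of class `selm_covariance_report`: `epsilon` (max
#'   absolute entrywise error), `max_z`, `n`, `pass`, and the matrices.
#' @export
increment_covariance_test <- function(state, model, dt = 1e-4, n = 1e4,
                                      z_limit = 5) {
  K <- dense_dissipative_operator(state, model)
  lay <- attr(K, "layout")
  y0 <- pack_state(state)
  g <- model$grid
  inc <- matrix(0, n, length(y0))
  for (i in seq_len(n)) {
    y1 <- pack_state(selm_step(state, dt, model))
    d <- y1 - y0
    if (!is.null(lay$X)) {
      d[lay$X[1]] <- min_image(d[lay$X[1]], g$Lx)
      d[lay$X[2]] <- min_image(d[lay$X[2]], g$Ly)
    }
    inc[i, ] <- d
  }
  emp <- stats::cov(inc)
  tgt <- 2 * model$params$kB * K * dt
  se <- sqrt(diag(tgt) %o% diag(tgt) + tgt^2) / sqrt(n)
  err <- emp - tgt
  z <- abs(err) / pmax(se, .Machine$double.xmin)
  z[se == 0 & abs(err) == 0] <- 0
  rep <- list(epsilon = max(abs(err)), max_z = max(z), n = n, dt = dt,
              pass = max(z) < z_limit,
              empirical = emp, target = tgt)
  class(rep) <- "selm_covariance_report"
  rep
}

#' @export
print.selm_covariance_report <- function(x, ...) {
  cat(sprintf(paste0("<increment covariance> n = %d, dt = %g, ",
                     "max |err| = %.3e, max |z| = %.2f  [%s]\n"),
              x$n, x$dt, x$epsilon, x$max_z, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Equilibrium-statistics suite
#'
#' Three classical closed-form checks of the particle dynamics and the
#' discrete energy balance:
#'
#' 1. *Boltzmann statistics in a harmonic well*: a long trajectory in
#'    `Psi = (k/2)|X - a|^2` at constant temperature must have per-axis
#'    position variance `kB theta / k` (equipartition), within 3 standard
#'    errors of the decorrelated sample count.
#' 2. *Free diffusion*: over `n_paths` independent paths the mean-square
#'    displacement per axis must grow as `2 kB theta / gamma_p * t`,
#'    within 5 percent.
#' 3. *Closed-system energy conservation*: with noise off and no ambient
#'    coupling, the total energy along a trajectory with an actively
#'    dissipating particle-species coupling must be constant to a relative
#'    drift below `1e-6` over `n_energy` steps (the heating terms exactly
#'    reclaim the mechanical losses).
#'
#' @param kB,theta0,gamma_p particle-level parameters (defaults: the
#'   hot-escape study's values).
#' @param k_spring harmonic stiffness for the Boltzmann check.
#' @param n_paths free-diffusion path count.
#' @param T_msd free-diffusion horizon.
#' @param n_energy steps for the conservation check.
#' @param seed RNG seed.
#' @return Object of class `selm_equilibrium_report` with one row per
#'   check: estimate, target, tolerance and pass flag.
#' @export
equilibrium_suite <- function(kB = 1e-5, theta0 = 3, gamma_p = 0.1,
                              k_spring = 1, n_paths = 1e4, T_msd = 0.1,
                              n_energy = 1000, seed = 1) {
  set.seed(seed)
  g <- selm_grid(20, 20, 0.1)
  p <- selm_params(kB = kB, theta0 = theta0, gamma_p = gamma_p,
                   kappaPI = 1, kappaCI = 0, kappaCC = 1, kappa0 = 0)

  # (a) harmonic-well Boltzmann variance
  ctr <- c(1, 1)
  mh <- selm_model(g, p, potential_harmonic(k_spring, ctr), active = "X")
  relax <- gamma_p / k_spring
  dt <- relax / 10
  stride <- 20L                      # ~2 relaxation times between samples
  n_samp <- 1e4L
  tr <- run_selm(selm_state(g, X = ctr), mh, dt, n_samp * stride,
                 record_stride = stride)
  xs <- min_image(tr$particle$X1 - ctr[1], g$Lx)
  ys <- min_image(tr$particle$X2 - ctr[2], g$Ly)
  v <- (stats::var(xs) + stats::var(ys)) / 2
  v_tgt <- kB * theta0 / k_spring
  n_eff <- n_samp                    # samples ~2 relaxation times apart
  v_se <- v_tgt * sqrt(2 / n_eff) * sqrt(2)  # two pooled axes, conservative
  boltz <- data.frame(check = "harmonic_variance", estimate = v,
                      target = v_tgt, tol = 3 * v_se,
                      pass = abs(v - v_tgt) < 3 * v_se)

  # (b) free-diffusion mean-square displacement slope
  mf <- selm_model(g, p, potential_none(), active = "X")
  nst <- max(1L, round(T_msd / 1e-3))
  d2 <- vapply(seq_len(n_paths), function(i) {
    tr <- run_selm(selm_state(g, X = ctr), mf, T_msd / nst, nst)
    sum(min_image(tr$final$X - ctr, g$Lx)^2)
  }, numeric(1))
  slope <- mean(d2) / 2 / T_msd      # per-axis MSD slope
  s_tgt <- 2 * kB * theta0 / gamma_p
  msd <- data.frame(check = "msd_slope", estimate = slope, target = s_tgt,
                    tol = 0.05 * s_tgt,
                    pass = abs(slope - s_tgt) < 0.05 * s_tgt)

  # (c) closed-system energy conservation with active coupling
  pc <- selm_params(kB = 0, c0 = 2.1, kappa_bar = 1.2e-3, gamma_p = 13,
                    kappaPI = 100, kappaCI = 30, kappaCC = 130, kappa0 = 0,
                    C_P = 1.2, C_C = 130, C_I = 140, theta0 = 3)
  pot <- potential_kernel_coupling(1.1, 0.2)
  mc <- selm_model(g, pc, pot,
                   interface_kernel = kernel_spec("gaussian", sigma0 = 0.2))
  st <- selm_state(g, X = c(0, 0),
                   q = gaussian_blob_field(g, c(1.5, 1.5), 0.2),
                   thetaP = 3, thetaI = 3, thetaC = cell_field(g, 3))
  E0 <- total_energy(st, mc)
  tr <- run_selm(st, mc, 2e-4, n_energy, noise = FALSE)
  drift <- abs(total_energy(tr$final, mc) - E0) / abs(E0)
  cons <- data.frame(check = "energy_conservation", estimate = drift,
                     target = 0, tol = 1e-6, pass = drift < 1e-6)

  rep <- list(results = rbind(boltz, msd, cons),
              pass = all(boltz$pass, msd$pass, cons$pass))
  class(rep) <- "selm_equilibrium_report"
  rep
}

#' @export
print.selm_equilibrium_report <- function(x, ...) {
  cat("<equilibrium suite>\n")
  print(x$results, row.names = FALSE, digits = 4)
  cat(sprintf("overall: %s\n", if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
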