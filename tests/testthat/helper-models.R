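# Shared fixtures: gentle, explicitly stable parameter sets and small
# fully-populated states used across the operator and dynamics tests.

stable_params <- function(kB = 1e-3) {
  selm_params(kB = kB, c0 = 1.5, kappa_bar = 0.02, gamma_p = 2,
              kappaPI = 5, kappaCI = 2, kappaCC = 0.5, kappa0 = 0.3,
              C_P = 1.2, C_C = 2, C_I = 1.5, theta0 = 3)
}

# full model on the 4x4 demo state with every block active
full_model_4x4 <- function(kB = 1e-3, kappa0 = 0.3, seed = 1) {
  fx <- demo_state_4x4(seed)
  p <- selm_params(kB = kB, c0 = 1.5, kappa_bar = 0.02, gamma_p = 2,
                   kappaPI = 5, kappaCI = 2, kappaCC = 0.5, kappa0 = kappa0,
                   C_P = 1.2, C_C = 2, C_I = 1.5, theta0 = 3)
  pot <- potential_kernel_coupling(k1 = 0.8, sigma0 = 0.3, r_cut = 0.9)
  m <- selm_model(fx$grid, p, pot,
                  interface_kernel = kernel_spec("gaussian", sigma0 = 0.3,
                                                 r_cut = 0.9))
  list(grid = fx$grid, state = fx$state, model = m)
}

# study-scale closed system (no ambient, noise off) with an actively
# dissipating particle-species coupling
closed_system_20x20 <- function() {
  g <- selm_grid(20, 20, 0.1)
  p <- selm_params(kB = 0, c0 = 2.1, kappa_bar = 1.2e-3, gamma_p = 13,
                   kappaPI = 100, kappaCI = 30, kappaCC = 130, kappa0 = 0,
                   C_P = 1.2, C_C = 130, C_I = 140, theta0 = 3)
  m <- selm_model(g, p, potential_kernel_coupling(1.1, 0.2),
                  interface_kernel = kernel_spec("gaussian", sigma0 = 0.2))
  st <- selm_state(g, X = c(0, 0),
                   q = gaussian_blob_field(g, c(1.5, 1.5), 0.2),
                   thetaP = 3, thetaI = 3, thetaC = cell_field(g, 3))
  list(grid = g, model = m, state = st)
}
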