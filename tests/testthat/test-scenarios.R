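test_that("sensors read uniform fields exactly and smooth sinusoids like fine quadrature", {
  g <- selm_grid(20, 20, 0.1)
  sens <- sensor_array(g)
  expect_equal(nrow(sens$positions), 20)

  # uniform field: every sensor reports theta0 up to the truncation defect
  Q <- sensed_temperature(cell_field(g, 3), sens)
  expect_lt(max(abs(Q - 3)), 3e-3)

  # sinusoidal field: matches a fine-grid quadrature of the continuum
  # integral at each sensor
  th <- sinusoid_temperature(g, 3, 0.5)
  Q <- sensed_temperature(th, sens)
  gf <- selm_grid(200, 200, 2 / 200)
  thf <- sinusoid_temperature(gf, 3, 0.5)
  zeta <- kernel_spec("gaussian", sigma0 = 0.1)
  for (i in c(1, 5, 11, 18)) {
    fine <- interpolate_field(thf, sens$positions[i, ], zeta, gf)
    expect_equal(Q[i], fine, tolerance = 5e-3)
  }

  # sensors half a period apart report deviations of opposite sign
  # (k = [2, 0] so the mode is periodic on the domain with period L)
  th2 <- sinusoid_temperature(g, 3, 0.5, c(2, 0))
  s2 <- sensor_array(g, positions = rbind(c(0.55, 1), c(0.55 + 1, 1)))
  Q2 <- sensed_temperature(th2, s2) - 3
  expect_lt(Q2[1] * Q2[2], 0)
})

test_that("the exponential response filter has the study's DC gain and limits", {
  # constant input theta0 = 3 with beta0 = 1/3: fixed point exactly 1
  I <- 0.2
  for (k in 1:4000) I <- update_filtered_signal(I, 3, 1e-5, 1e4, 1 / 3)
  expect_equal(I, 1, tolerance = 1e-10)

  # memoryless limit tracks beta0 * Q instantly
  expect_equal(update_filtered_signal(5, 2.4, 1, 1e12, 1 / 3), 0.8)

  # matches a direct Riemann-sum evaluation of the convolution to O(dt)
  set.seed(12)
  dt <- 1e-5; lambda <- 1e4; beta0 <- 1 / 3
  Q <- 3 + cumsum(rnorm(4000, sd = 0.01))
  I <- beta0 * Q[1]
  for (k in seq_along(Q)) I <- update_filtered_signal(I, Q[k], dt, lambda, beta0)
  tk <- length(Q) * dt
  riemann <- beta0 * sum(lambda * exp(-lambda * (tk - seq_along(Q) * dt)) *
                           Q * dt) +
    beta0 * Q[1] * exp(-lambda * tk)  # pre-charge carried from t = 0
  expect_equal(I, riemann, tolerance = 0.06)  # O(lambda dt) quadrature gap

  expect_error(update_filtered_signal(1, 1, 1e-5, -2, 1 / 3), "lambda")
})

test_that("a frozen concentration blob acts as a static attractor: y rises to 1", {
  g <- selm_grid(20, 20, 0.1)
  p <- selm_params(kB = 0, c0 = 2.1, kappa_bar = 1.2e-3, gamma_p = 13)
  m <- selm_model(g, p, potential_kernel_coupling(1.1, 0.2),
                  active = "X")  # q present but frozen, noise off
  st <- selm_state(g, X = c(0, 0),
                   q = gaussian_blob_field(g, c(1.5, 1.5), 0.2))
  tr <- run_selm(st, m, 1e-3, 12000, record_stride = 1000, noise = FALSE)
  y <- min_image(tr$particle$X2, g$Ly) / min_image(1.5, g$Ly)
  expect_equal(y[length(y)], 1, tolerance = 0.02)
  # monotone approach after the transient
  expect_true(all(diff(y[3:length(y)]) > -1e-9))
})

test_that("scenario configs echo their presets and reject unknown keys", {
  cfg <- scenario_config("escape")
  expect_equal(cfg$c2, 1.5e-4)
  expect_equal(cfg$X0, c(5 / 3, 1.0))
  expect_equal(cfg$dt, 3e-3)
  cfg2 <- scenario_config("escape", r0 = 0.5, n_reps = 3)
  expect_equal(cfg2$r0, 0.5)
  expect_error(scenario_config("escape", bogus_key = 1), "unknown config")

  # replicate seeds are distinct and reproducible
  s1 <- replicate_seeds(4, 50)
  s2 <- replicate_seeds(4, 50)
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0)
})

test_that("well lattice is staggered, commensurate, and contains the start well", {
  ctr <- well_lattice_centers(2, 2, 2 / 3)
  expect_equal(nrow(ctr), 9)
  # includes the escape-study well center
  d <- sqrt((ctr[, 1] - 5 / 3)^2 + (ctr[, 2] - 1)^2)
  expect_lt(min(d), 1e-12)
  # rows alternate offsets (staggered)
  rows <- split(ctr[, 1], round(ctr[, 2], 6))
  offs <- vapply(rows, min, numeric(1))
  expect_gt(max(offs) - min(offs), 0.3)
  expect_error(well_lattice_centers(2, 2, 0.55), "divide")
})

test_that("a noise-free particle at a well center never escapes (censored)", {
  cfg <- scenario_config("escape", n_reps = 1, c3 = 0, T_max = 3,
                         noise = FALSE)
  res <- run_hot_escape(cfg)
  expect_true(all(res$censored))
  expect_equal(res$escape_time, cfg$T_max)
})

test_that("positioning runs report y within the physical band and respond to diffusivity", {
  cfg <- scenario_config("positioning", n_reps = 3, T_end = 6,
                         kappa_bar = c(1.2e-3, 3.6e-1))
  res <- run_concentration_positioning(cfg)
  expect_equal(nrow(res), 6)
  agg <- tapply(res$y, res$kappa_bar, mean)
  # replicate means stay in the stochastic neighborhood of [0, 1]
  expect_true(all(agg > -0.1 & agg < 1.1))
  # slow species -> protein reaches the source; fast species -> it stays
  expect_gt(agg[["0.0012"]], 0.8)
  expect_lt(agg[["0.36"]], 0.3)
})

test_that("escape summary enters censored replicates at the horizon", {
  runs <- data.frame(c2 = 1, c3 = c(0, 0, 1, 1), replicate = c(1, 2, 1, 2),
                     escape_time = c(10, 10, 2, 4),
                     censored = c(TRUE, TRUE, FALSE, FALSE))
  s <- summarize_escape(runs)
  expect_equal(s$mean_escape, c(10, 3))
  expect_equal(s$n_censored, c(2, 0))
})
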