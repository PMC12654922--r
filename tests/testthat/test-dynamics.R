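test_that("uniform equilibrium states are fixed points of the drift", {
  fx <- full_model_4x4(kappa0 = 0.3)
  g <- fx$grid
  # uniform q and temperatures equal to the bath, no potential
  m <- selm_model(g, fx$model$params, potential_none(),
                  interface_kernel = kernel_spec("gaussian", sigma0 = 0.3,
                                                 r_cut = 0.9))
  st <- selm_state(g, X = c(0.9, 1.1), q = cell_field(g, 1),
                   thetaP = 3, thetaI = 3, thetaC = cell_field(g, 3))
  a <- deterministic_drift(st, m)
  expect_equal(a$X, c(0, 0))
  expect_equal(a$q, matrix(0, 4, 4))
  expect_equal(a$thetaP, 0)
  expect_equal(a$thetaI, 0)
  expect_equal(a$thetaC, matrix(0, 4, 4))
})

test_that("two-temperature relaxation follows the closed-form exponential", {
  g <- selm_grid(4, 4, 0.5)
  p <- selm_params(kB = 0, kappaPI = 5, kappaCI = 0, kappaCC = 1,
                   kappa0 = 0, C_P = 1.2, C_I = 1.5, theta0 = 3)
  m <- selm_model(g, p, active = c("thetaP", "thetaI"))
  st <- selm_state(g, thetaP = 4, thetaI = 2.5)
  # closed form: difference decays at kPI (1/C_P + 1/C_I); weighted sum constant
  lam <- p$kappaPI * (1 / p$C_P + 1 / p$C_I)
  Tend <- 0.5
  exact <- function(t) {
    mean_w <- (p$C_P * 4 + p$C_I * 2.5) / (p$C_P + p$C_I)
    d <- (4 - 2.5) * exp(-lam * t)
    c(thP = mean_w + d * p$C_I / (p$C_P + p$C_I),
      thI = mean_w - d * p$C_P / (p$C_P + p$C_I))
  }
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(dt) {
    tr <- run_selm(st, m, dt, round(Tend / dt), noise = FALSE)
    ex <- exact(Tend)
    max(abs(c(tr$final$thetaP - ex["thP"], tr$final$thetaI - ex["thI"])))
  }, numeric(1))
  # capacity-weighted mean conserved; second-order decay of the error
  expect_lt(errs[1], 1e-4)
  expect_gt(errs[1] / errs[2], 3.4)  # ~4x per halving (O(dt^2))
  expect_gt(errs[2] / errs[3], 3.4)

  # conservation of C_P thetaP + C_I thetaI along the way
  tr <- run_selm(st, m, 1e-2, 50, noise = FALSE)
  expect_equal(p$C_P * tr$final$thetaP + p$C_I * tr$final$thetaI,
               p$C_P * 4 + p$C_I * 2.5, tolerance = 1e-12)
})

test_that("hot-escape preset relaxes the particle temperature at kPI / C_P", {
  p3 <- selm_preset("table3")
  expect_equal(p3$kappaPI / p3$C_P, 5.7e2 / 9.3e2)
  expect_equal(p3$kappaPI / p3$C_P, 0.6129, tolerance = 1e-4)
})

test_that("the stepper is the identity without drift and noise, and Euler-Maruyama for additive noise", {
  g <- selm_grid(4, 4, 0.5)
  p <- selm_params(kB = 0, theta0 = 3)
  m <- selm_model(g, p, active = "X")
  st <- selm_state(g, X = c(0.4, 0.6))
  expect_equal(selm_step(st, 0.1, m)$X, st$X)

  # constant-temperature particle: noise amplitude is state-independent,
  # so predictor and corrector noise coincide (one Euler-Maruyama step)
  p2 <- selm_params(kB = 1e-3, gamma_p = 2, theta0 = 3)
  m2 <- selm_model(g, p2, active = "X")
  dt <- 0.01
  set.seed(9)
  s1 <- selm_step(st, dt, m2)
  set.seed(9)
  xi <- rnorm(2)
  expect_equal(s1$X, st$X + sqrt(2 * p2$kB * dt * 3 / 2) * xi)
})

test_that("closed-system energy is conserved and entropy does not decrease", {
  cs <- closed_system_20x20()
  E0 <- total_energy(cs$state, cs$model)
  S0 <- total_entropy(cs$state, cs$model)
  tr <- run_selm(cs$state, cs$model, 2e-4, 1000, noise = FALSE)
  expect_lt(abs(total_energy(tr$final, cs$model) - E0) / abs(E0), 1e-6)
  expect_gt(total_entropy(tr$final, cs$model), S0)

  # the semi-discrete energy rate vanishes identically at the initial state
  a <- deterministic_drift(cs$state, cs$model)
  ge <- energy_gradient(cs$state, cs$model)
  g <- cs$grid
  rate <- sum(ge$X * a$X) + sum(ge$q * a$q) * g$dV +
    ge$thetaP * a$thetaP + ge$thetaI * a$thetaI +
    sum(ge$thetaC * a$thetaC) * g$dV
  expect_lt(abs(rate), 1e-10)
})

test_that("species mass is conserved to machine precision with noise on", {
  fx <- full_model_4x4(kB = 1e-3)
  set.seed(10)
  mass0 <- sum(fx$state$q) * fx$grid$dV
  tr <- run_selm(fx$state, fx$model, 1e-3, 1000)
  expect_equal(sum(tr$final$q) * fx$grid$dV, mass0, tolerance = 1e-13)
})

test_that("compiled run reproduces the R stepper draw-for-draw", {
  fx <- full_model_4x4(kB = 1e-3)
  set.seed(21)
  tr <- run_selm(fx$state, fx$model, 5e-4, 5)
  set.seed(21)
  s <- fx$state
  for (i in 1:5) s <- selm_step(s, 5e-4, fx$model)
  expect_equal(tr$final$X, s$X, tolerance = 1e-10)
  expect_equal(tr$final$q, s$q, tolerance = 1e-10)
  expect_equal(tr$final$thetaP, s$thetaP, tolerance = 1e-10)
  expect_equal(tr$final$thetaI, s$thetaI, tolerance = 1e-10)
  expect_equal(tr$final$thetaC, s$thetaC, tolerance = 1e-10)

  # and the deterministic drift agrees between the two paths
  set.seed(33)
  trd <- run_selm(fx$state, fx$model, 5e-4, 3, noise = FALSE)
  set.seed(33)
  sd_ <- fx$state
  for (i in 1:3) sd_ <- selm_step(sd_, 5e-4, fx$model, noise = FALSE)
  expect_equal(trd$final$thetaC, sd_$thetaC, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  fx <- full_model_4x4(kB = 1e-3)
  set.seed(77)
  a <- run_selm(fx$state, fx$model, 1e-3, 20)
  set.seed(77)
  b <- run_selm(fx$state, fx$model, 1e-3, 20)
  expect_identical(a$final, b$final)
})

test_that("two-stage scheme matches a Stratonovich (Ito-corrected) reference for multiplicative noise", {
  # two-temperature exchange: noise amplitude sqrt(kPI thetaP thetaI) is
  # state-dependent.  An Ito-Euler reference needs the explicit
  # kB (div K) drift; the package's Heun scheme must reproduce the same
  # law without it.
  g <- selm_grid(4, 4, 0.5)
  kB <- 5e-3; kPI <- 4; CP <- 1.0; CI <- 2.0
  p <- selm_params(kB = kB, kappaPI = kPI, kappaCI = 0, kappaCC = 1,
                   kappa0 = 0, C_P = CP, C_I = CI, theta0 = 3)
  m <- selm_model(g, p, active = c("thetaP", "thetaI"))
  st <- selm_state(g, thetaP = 3.5, thetaI = 2.8)
  dt <- 2e-3; n_steps <- 100; n_paths <- 1500

  set.seed(14)
  heun <- vapply(seq_len(n_paths), function(i)
    run_selm(st, m, dt, n_steps)$final$thetaP, numeric(1))

  # independent Ito-Euler oracle carrying the explicit Stratonovich
  # correction kB (dR/dY) : R for the rank-one exchange factor
  # deterministic part integrated with the same two-stage accuracy so the
  # paired comparison isolates the treatment of the multiplicative noise
  ito_ref <- function(seed, with_correction) {
    set.seed(seed)
    vapply(seq_len(n_paths), function(i) {
      thP <- 3.5; thI <- 2.8
      for (k in seq_len(n_steps)) {
        xi <- rnorm(1)
        aP <- function(p_, i_) -kPI / CP * (p_ - i_)
        aI <- function(p_, i_) kPI / CI * (p_ - i_)
        pP <- thP + aP(thP, thI) * dt; pI <- thI + aI(thP, thI) * dt
        corr_P <- kB * kPI / 2 * (thI / CP^2 - thP / (CP * CI))
        corr_I <- kB * kPI / 2 * (thP / CI^2 - thI / (CP * CI))
        a <- sqrt(2 * kB * kPI * thP * thI * dt) * xi
        thP2 <- thP + (aP(thP, thI) + aP(pP, pI)) / 2 * dt +
          with_correction * corr_P * dt + a / CP
        thI2 <- thI + (aI(thP, thI) + aI(pP, pI)) / 2 * dt +
          with_correction * corr_I * dt - a / CI
        thP <- thP2; thI <- thI2
      }
      thP
    }, numeric(1))
  }
  # same seed: the references consume the identical draw sequence (one
  # normal per step), so the comparison is paired and sharp
  d1 <- heun - ito_ref(14, 1)
  d0 <- heun - ito_ref(14, 0)
  expect_lt(abs(mean(d1)), 4 * sd(d1) / sqrt(n_paths))
  expect_gt(abs(mean(d0)), 4 * sd(d0) / sqrt(n_paths))
  expect_gt(abs(mean(d0)), 5 * abs(mean(d1)))
})
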