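test_that("total energy matches the closed-form sum for uniform temperatures", {
  g <- selm_grid(20, 20, 0.1)
  p <- selm_params(kB = 1e-5, C_P = 1.2, C_C = 1.3e2, C_I = 1.4e2,
                   theta0 = 3)
  m <- selm_model(g, p, potential_none())
  st <- selm_state(g, X = c(1, 1), q = cell_field(g, 1),
                   thetaP = 3, thetaI = 3, thetaC = cell_field(g, 3))
  # Psi = Phi = 0: E = theta0 * (C_P + C_I + C_C * |Omega|) = 3 * 661.2
  expect_equal(total_energy(st, m), 1983.6)

  # linearity in the temperatures
  st2 <- selm_state(g, X = c(1, 1), q = cell_field(g, 1),
                    thetaP = 6, thetaI = 6, thetaC = cell_field(g, 6))
  expect_equal(total_energy(st2, m), 2 * total_energy(st, m))
})

test_that("total entropy has its closed form and is maximized by uniform q", {
  g <- selm_grid(20, 20, 0.1)
  p <- selm_params(C_P = 1.2, C_C = 1.3e2, C_I = 1.4e2, theta0 = 3)
  m <- selm_model(g, p)
  st <- selm_state(g, q = cell_field(g, 1), thetaP = 3, thetaI = 3,
                   thetaC = cell_field(g, 3))
  # q = 1 contributes zero; uniform temperatures give the log closed form
  expect_equal(total_entropy(st, m),
               (1.2 + 140 + 130 * 4) * log(3))

  # -sum q log q at fixed mass is maximal for uniform q
  set.seed(5)
  s_unif <- total_entropy(st, m)
  for (i in 1:5) {
    pert <- bandlimited_field(g, kmax = 2, amp = 0.5, mu = 1)
    pert <- pert * (sum(st$q) / sum(pert))  # same total mass
    stp <- selm_state(g, q = pert, thetaP = 3, thetaI = 3,
                      thetaC = cell_field(g, 3))
    expect_lt(total_entropy(stp, m), s_unif)
  }

  # nonpositive temperatures are rejected at the functional level
  bad <- st
  bad$thetaC[1, 1] <- -0.5
  expect_error(total_entropy(bad, m), "temperature")
})

test_that("entropy gradient blocks follow the analytic forms and finite differences", {
  fx <- full_model_4x4()
  st <- fx$state; m <- fx$model; g <- fx$grid
  gr <- entropy_gradient(st, m)
  expect_equal(gr$X, c(0, 0))
  expect_equal(gr$thetaP, m$params$C_P / st$thetaP)
  expect_equal(gr$thetaI, m$params$C_I / st$thetaI)
  expect_equal(gr$thetaC, m$params$C_C / st$thetaC)
  expect_equal(gr$q, -m$params$c0 * (1 + log(st$q)))

  # theta_P = 3, C_P = 1.2 gives dS/dthetaP = 0.4
  p12 <- selm_params(C_P = 1.2)
  st3 <- selm_state(g, thetaP = 3, thetaI = 3, thetaC = cell_field(g, 3))
  expect_equal(entropy_gradient(st3, selm_model(g, p12))$thetaP, 0.4)

  # finite-difference oracle (functional derivative = dS/dvalue / dV)
  h <- 1e-6
  num <- function(mutate) {
    s1 <- st; s2 <- st
    s1 <- mutate(s1, -h); s2 <- mutate(s2, +h)
    (total_entropy(s2, m) - total_entropy(s1, m)) / (2 * h)
  }
  expect_equal(num(function(s, d) { s$thetaP <- s$thetaP + d; s }),
               gr$thetaP, tolerance = 1e-6)
  expect_equal(num(function(s, d) { s$q[2, 3] <- s$q[2, 3] + d; s }) / g$dV,
               gr$q[2, 3], tolerance = 1e-5)
  expect_equal(num(function(s, d) { s$thetaC[1, 4] <- s$thetaC[1, 4] + d; s }) /
                 g$dV, gr$thetaC[1, 4], tolerance = 1e-5)
})

test_that("energy gradient blocks match the analytic forms and finite differences", {
  fx <- full_model_4x4()
  st <- fx$state; m <- fx$model; g <- fx$grid
  gr <- energy_gradient(st, m)
  expect_equal(gr$thetaP, m$params$C_P)
  expect_equal(gr$thetaI, m$params$C_I)
  expect_equal(gr$thetaC, cell_field(g, m$params$C_C))
  expect_equal(gr$q, m$params$c0 * m$potential$phi_cells(g, st$X))

  # X block against finite differences of the total energy
  h <- 1e-6
  for (d in 1:2) {
    s1 <- st; s2 <- st
    s1$X[d] <- s1$X[d] - h; s2$X[d] <- s2$X[d] + h
    num <- (total_energy(s2, m) - total_energy(s1, m)) / (2 * h)
    expect_equal(gr$X[d], num, tolerance = 1e-5)
  }

  # harmonic potential: X block is k (X - a)
  mh <- selm_model(g, m$params, potential_harmonic(2.5, c(0.8, 1.0)))
  sth <- selm_state(g, X = c(1.1, 1.2), thetaP = 3, thetaI = 3,
                    thetaC = cell_field(g, 3))
  expect_equal(energy_gradient(sth, mh)$X, 2.5 * c(0.3, 0.2))
})

test_that("protein force is restoring at well centers and points up concentration gradients", {
  g <- selm_grid(20, 20, 0.1)
  p <- selm_params()
  # single well: zero force at the center, restoring nearby
  pot <- potential_well_lattice(1.5e-4, 0.2, matrix(c(1, 1), 1))
  m <- selm_model(g, p, pot)
  st0 <- selm_state(g, X = c(1, 1), thetaP = 3, thetaI = 3,
                    thetaC = cell_field(g, 3))
  expect_equal(protein_force(st0, m), c(0, 0))
  st1 <- selm_state(g, X = c(1.1, 1), thetaP = 3, thetaI = 3,
                    thetaC = cell_field(g, 3))
  f1 <- protein_force(st1, m)
  expect_lt(f1[1], 0)  # pulled back toward the center
  expect_equal(f1[1], -1.5e-4 * (0.1 / 0.04) * exp(-0.01 / 0.08),
               tolerance = 1e-12)  # closed-form lattice force
  expect_equal(f1[2], 0)

  # kernel coupling on uniform q: symmetric, force ~ 0
  mk <- selm_model(g, p, potential_kernel_coupling(1.1, 0.2))
  stu <- selm_state(g, X = c(0.8, 1.2), q = cell_field(g, 1))
  expect_lt(max(abs(protein_force(stu, mk))), 1e-10)

  # displaced blob: attractive coupling pulls toward the blob (+x), and the
  # magnitude matches a fine-grid quadrature of the continuum integral
  blob <- gaussian_blob_field(g, c(1.3, 1.0), 0.2)
  stb <- selm_state(g, X = c(0.9, 1.0), q = blob)
  fb <- protein_force(stb, mk)
  expect_gt(fb[1], 0)
  expect_equal(abs(fb[2]), 0, tolerance = 1e-10)

  # with Phi = -eta: F_x = c0 dV sum (s_x / sigma0^2) eta(s) q(x_m)
  quad_force_x <- function(n) {
    gf <- selm_grid(n, n, 2 / n)
    qf <- gaussian_blob_field(gf, c(1.3, 1.0), 0.2)
    eta <- kernel_spec("gaussian", sigma0 = 0.2, k1 = 1.1)
    sx <- outer(min_image(gf$xc - 0.9, 2), rep(1, n))
    sy <- outer(rep(1, n), min_image(gf$yc - 1.0, 2))
    p$c0 * gf$dV * sum(sx / 0.04 * kernel_eval(eta, sx, sy) * qf)
  }
  expect_equal(fb[1], quad_force_x(160), tolerance = 2e-3)
})
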