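test_that("gaussian kernel evaluates to its closed form with study widths", {
  eta <- kernel_spec("gaussian", sigma0 = 0.2, k1 = 1.1)
  expect_equal(kernel_eval(eta, 0, 0), 1.1 / (2 * pi * 0.04))
  expect_equal(kernel_eval(eta, 0, 0), 4.3768, tolerance = 1e-4)

  zeta <- kernel_spec("gaussian", sigma0 = 0.1)
  expect_equal(kernel_eval(zeta, 0, 0), 1 / (2 * pi * 0.01))
  expect_equal(kernel_eval(zeta, 0, 0), 15.9155, tolerance = 1e-4)

  # radial symmetry and truncation
  s <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  expect_equal(kernel_eval(eta, s[, 1], s[, 2]),
               kernel_eval(eta, -s[, 1], -s[, 2]))
  expect_identical(kernel_eval(eta, eta$r_cut + 1e-9, 0), 0)
})

test_that("unit kernel integrates to one within the truncation defect", {
  g <- selm_grid(20, 20, 0.1)
  zeta <- kernel_spec("gaussian", sigma0 = 0.1)
  mass <- interpolate_field(cell_field(g, 1), c(0.77, 1.31), zeta, g)
  expect_lt(abs(mass - 1), 1e-3)
})

test_that("interpolation sifts point masses and matches refined quadrature", {
  g <- selm_grid(20, 20, 0.1)
  zeta <- kernel_spec("gaussian", sigma0 = 0.1)
  X <- c(0.52, 1.08)
  # point mass of weight 1/dV at the cell nearest X
  f <- cell_field(g, 0)
  f[6, 11] <- 1 / g$dV  # cell center (0.55, 1.05)
  expect_equal(interpolate_field(f, X, zeta, g),
               kernel_eval(zeta, 0.55 - 0.52, 1.05 - 1.08))

  # smooth gaussian field: refined-grid quadrature oracle, O(dx^2)
  field_fun <- function(x, y)
    1 + exp(-((x - 1.1)^2 + (y - 0.9)^2) / (2 * 0.3^2))
  coarse <- interpolate_field(outer(g$xc, g$yc, field_fun), X, zeta, g)
  gf <- selm_grid(160, 160, 2 / 160)
  fine <- interpolate_field(outer(gf$xc, gf$yc, field_fun), X, zeta, gf)
  expect_equal(coarse, fine, tolerance = 1e-3)
})

test_that("interpolation is translation-equivariant by whole cells", {
  g <- selm_grid(20, 20, 0.1)
  zeta <- kernel_spec("gaussian", sigma0 = 0.15)
  set.seed(4)
  f <- bandlimited_field(g, kmax = 2, amp = 0.4, mu = 2)
  X <- c(0.72, 1.33)
  v1 <- interpolate_field(f, X, zeta, g)
  f_shift <- f[c(20, 1:19), ]  # shift field by +dx in x
  v2 <- interpolate_field(f_shift, c(X[1] + g$dx, X[2]), zeta, g)
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("kernel support beyond half the domain is rejected", {
  g <- selm_grid(4, 4, 0.25)  # domain 1 x 1
  wide <- kernel_spec("gaussian", sigma0 = 0.2)  # r_cut = 0.8 > 0.5
  expect_error(interpolate_field(cell_field(g, 1), c(0.5, 0.5), wide, g),
               "half the periodic domain")
})

test_that("spread kernel gradient is odd, vanishes at the center, and matches finite differences", {
  g <- selm_grid(20, 20, 0.1)
  eta <- kernel_spec("gaussian", sigma0 = 0.2, k1 = 1.1)
  X <- c(0.95, 1.05)  # exactly at a cell center
  gr <- spread_kernel_gradient(X, eta, g)
  expect_equal(gr$x[10, 11], 0)
  expect_equal(gr$y[10, 11], 0)

  # antisymmetry under reflection through X (cells at X +- one cell)
  expect_equal(gr$x[11, 11], -gr$x[9, 11])
  expect_equal(gr$y[10, 12], -gr$y[10, 10])

  # finite-difference oracle: d/dX eta(x_m - X) = -grad_x eta
  h <- 1e-5
  for (cell in list(c(10, 11), c(12, 13), c(8, 9))) {
    xm <- c(g$xc[cell[1]], g$yc[cell[2]])
    num <- (kernel_eval(eta, min_image(xm[1] - (X[1] + h), g$Lx),
                        min_image(xm[2] - X[2], g$Ly)) -
            kernel_eval(eta, min_image(xm[1] - (X[1] - h), g$Lx),
                        min_image(xm[2] - X[2], g$Ly))) / (2 * h)
    expect_equal(-gr$x[cell[1], cell[2]], num, tolerance = 1e-6)
  }
})

test_that("peskin delta kernel has unit partition sums on the mesh", {
  g <- selm_grid(20, 20, 0.1)
  pk <- kernel_spec("peskin_delta", sigma0 = g$dx)
  for (X in list(c(0.5, 0.5), c(0.537, 1.112))) {
    mass <- interpolate_field(cell_field(g, 1), X, pk, g)
    expect_equal(mass, 1, tolerance = 1e-12)
  }
})
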