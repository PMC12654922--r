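test_that("every dissipative block factorizes exactly: R R^T = K, symmetric PSD", {
  fx <- full_model_4x4(kB = 1e-3)
  blocks <- dissipative_blocks(fx$state, fx$model)
  expect_setequal(vapply(blocks, `[[`, "", "label"),
                  c("protein", "q", "conduction", "PI", "IC", "ambient"))
  for (b in blocks) {
    R <- b$dense_R()
    K <- b$dense_K()
    expect_lt(max(abs(R %*% t(R) - K)), 1e-12)
    expect_equal(K, t(K))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10 * max(abs(ev)))
  }
})

test_that("conserved-field blocks annihilate constants and conserve per draw", {
  fx <- full_model_4x4(kB = 1e-3)
  g <- fx$grid
  blocks <- dissipative_blocks(fx$state, fx$model)
  lab <- vapply(blocks, `[[`, "", "label")
  qb <- blocks[[which(lab == "q")]]
  lay <- attr(blocks, "layout")

  # K_q applied to a constant conjugate vector gives zero (null-space
  # alignment with mass conservation)
  v <- numeric(length(pack_state(fx$state)))
  v[lay$q] <- 1
  expect_lt(max(abs(qb$apply(v))), 1e-12)

  # each species draw sums to zero over the grid exactly
  set.seed(6)
  for (i in 1:20) {
    h <- qb$factor_apply(rnorm(qb$n_xi))
    expect_lt(abs(sum(h[lay$q]) * g$dV), 1e-13)
  }
  cb <- blocks[[which(lab == "conduction")]]
  h <- cb$factor_apply(rnorm(cb$n_xi))
  expect_lt(abs(sum(h[lay$thetaC])), 1e-12)
})

test_that("fluctuations vanish at kB = 0 and are zero-mean at finite kB", {
  fx0 <- full_model_4x4(kB = 0)
  s <- sample_fluctuations(fx0$state, fx0$model, 1e-3)
  expect_length(s$xi, 0)
  expect_true(all(vapply(s$h, is.null, logical(1))))

  fx <- full_model_4x4(kB = 1e-3)
  set.seed(7)
  n <- 5000
  acc <- 0
  for (i in seq_len(n)) {
    s <- sample_fluctuations(fx$state, fx$model, 1e-3)
    acc <- acc + s$h$thetaP
  }
  # mean of n draws within 4 standard errors of zero
  sd1 <- sqrt(2 * fx$model$params$kB * 1e-3 *
                fx$model$params$kappaPI * fx$state$thetaP * fx$state$thetaI) /
    fx$model$params$C_P
  expect_lt(abs(acc / n), 4 * sd1 / sqrt(n))
})

test_that("sampled fluctuation covariance matches 2 kB K dt blockwise", {
  fx <- full_model_4x4(kB = 1e-3)
  blocks <- dissipative_blocks(fx$state, fx$model)
  lab <- vapply(blocks, `[[`, "", "label")
  pi_b <- blocks[[which(lab == "PI")]]
  amb <- blocks[[which(lab == "ambient")]]
  set.seed(8)
  n <- 5e4
  # exchange block: a rank-one factor, so a scalar variance check is sharp
  draws <- vapply(seq_len(n), function(i)
    pi_b$factor_apply(rnorm(1)), numeric(length(pack_state(fx$state))))
  K <- pi_b$dense_K()
  emp <- tcrossprod(draws) / n
  se <- sqrt((diag(K) %o% diag(K) + K^2) / n)
  nz <- se > 0
  expect_lt(max(abs(emp - K)[nz] / se[nz]), 5)
  # diagonal block: empirical variances against the dense diagonal
  dK <- diag(amb$dense_K())
  v <- rowMeans(vapply(seq_len(2000), function(i)
    amb$factor_apply(rnorm(amb$n_xi))^2,
    numeric(length(pack_state(fx$state)))))
  nz <- dK > 0
  expect_lt(max(abs(v[nz] - dK[nz]) / (dK[nz] * sqrt(2 / 2000))), 5)
})

test_that("the assembled operator covers exactly the drift's dissipative couplings", {
  fx <- full_model_4x4(kB = 1e-3)
  K <- dense_dissipative_operator(fx$state, fx$model)
  lay <- attr(K, "layout")
  # X block is the scaled mobility thetaP M
  expect_equal(K[lay$X, lay$X],
               diag(2) * fx$state$thetaP / fx$model$params$gamma_p)
  # no spurious coupling between the particle position and the fields
  expect_true(all(K[lay$X, c(lay$q, lay$thetaC)] == 0))
  # exchange couplings present with negative sign (heat flows between
  # reservoirs with opposite increments)
  expect_lt(K[lay$thetaP, lay$thetaI], 0)
  expect_true(all(K[lay$thetaC, lay$thetaI] <= 0))
})
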