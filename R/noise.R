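# Dissipative operator blocks K^(j), their factors R^(j) (R R^T = K), and
# dense forms for small-grid verification.  The factors are the
# divergence-form constructions: conserved-field noise is generated on
# faces and pushed through the discrete divergence, so it lives in the
# range of D and conserves the field sum exactly; scalar exchanges are
# rank-one antisymmetric differences with geometric-mean temperature
# amplitudes.

# R_j xi_j without the sqrt(2 kB dt) amplitude, state-shaped
block_factor_apply <- function(label, state, model, xi) {
  p <- model$params; g <- model$grid
  h <- list(X = NULL, q = NULL, thetaP = NULL, thetaI = NULL, thetaC = NULL)
  thC <- if (!is.null(state$thetaC)) state$thetaC else cell_field(g, p$theta0)
  thC_f <- cells_to_faces(thC, g)
  switch(label,
    protein = {
      thP <- if (!is.null(state$thetaP)) state$thetaP else p$theta0
      h$X <- sqrt(thP / p$gamma_p) * xi
    },
    q = {
      q_f <- cells_to_faces(pmax(state$q, 0), g)
      cf <- list(x = sqrt(thC_f$x * q_f$x / (p$gamma * p$c0 * g$dV)) * xi$x,
                 y = sqrt(thC_f$y * q_f$y / (p$gamma * p$c0 * g$dV)) * xi$y)
      h$q <- fv_divergence(cf, g)
    },
    conduction = {
      cf <- list(x = sqrt(p$kappaCC / g$dV) * thC_f$x * xi$x,
                 y = sqrt(p$kappaCC / g$dV) * thC_f$y * xi$y)
      h$thetaC <- fv_divergence(cf, g) / p$C_C
    },
    PI = {
      a <- sqrt(p$kappaPI * state$thetaP * state$thetaI) * xi
      h$thetaP <- a / p$C_P
      h$thetaI <- -a / p$C_I
    },
    IC = {
      kCI <- interface_conductivity(model, state$X)
      a <- sqrt(kCI * g$dV * state$thetaI * thC) * xi
      h$thetaC <- a / (p$C_C * g$dV)
      h$thetaI <- -sum(a) / p$C_I
    },
    ambient = {
      h$thetaC <- sqrt(p$kappa0 * thC * model$ambient / g$dV) / p$C_C * xi
    },
    stop("unknown block ", label))
  h
}

# number of standard normals consumed by a block
block_xi_length <- function(label, grid) {
  N <- grid$nx * grid$ny
  switch(label, protein = 2L, q = 2L * N, conduction = 2L * N,
         PI = 1L, IC = N, ambient = N)
}

block_xi_unflatten <- function(label, v, grid) {
  N <- grid$nx * grid$ny
  switch(label,
    protein = v,
    q = ,
    conduction = list(x = matrix(v[seq_len(N)], grid$nx, grid$ny),
                      y = matrix(v[N + seq_len(N)], grid$nx, grid$ny)),
    PI = v,
    IC = ,
    ambient = matrix(v, grid$nx, grid$ny))
}

# which state components a block writes
block_components <- function(label) {
  switch(label, protein = "X", q = "q", conduction = "thetaC",
         PI = c("thetaP", "thetaI"), IC = c("thetaC", "thetaI"),
         ambient = "thetaC")
}

#' Layout of the packed state vector
#'
#' The dense-operator machinery works on the flat state vector ordered as
#' `[X (2), q (N), thetaP, thetaI, thetaC (N)]`, with absent components
#' skipped and fields in column-major (x-fastest) cell order.
#'
#' @param state a [selm_state()].
#' @return Named list of index vectors into the packed state.
#' @export
state_layout <- function(state) {
  lay <- list(); i <- 0L
  add <- function(lay, comp, n) {
    lay[[comp]] <- i + seq_len(n); lay
  }
  if (!is.null(state$X)) { lay <- add(lay, "X", 2L); i <- i + 2L }
  if (!is.null(state$q)) { n <- length(state$q); lay <- add(lay, "q", n); i <- i + n }
  if (!is.null(state$thetaP)) { lay <- add(lay, "thetaP", 1L); i <- i + 1L }
  if (!is.null(state$thetaI)) { lay <- add(lay, "thetaI", 1L); i <- i + 1L }
  if (!is.null(state$thetaC)) { n <- length(state$thetaC); lay <- add(lay, "thetaC", n) }
  lay
}

#' @rdname state_layout
#' @export
pack_state <- function(state) {
  unlist(lapply(c("X", "q", "thetaP", "thetaI", "thetaC"), function(comp) {
    v <- state[[comp]]
    if (is.null(v)) NULL else as.vector(v)
  }))
}

#' Assemble the dissipative operator blocks
#'
#' Returns the list of state-dependent symmetric positive semidefinite
#' blocks `K^(j)` for the current state, each with its factor.  Every block
#' offers `factor_apply(xi)` (the action of `R^(j)` on standard normals,
#' returned as a packed state vector), `apply(v)` (the action of `K^(j)`),
#' and on small grids `dense_R()` / `dense_K()`, where `dense_K` is built
#' independently from the operator formulas so `R R^T = K` is a genuine
#' cross-check of the factorization.
#'
#' @inheritParams deterministic_drift
#' @return List of `selm_dissipative_block` objects (possibly empty when
#'   `kB = 0`); attribute `layout` carries the packed-state indexing.
#' @export
dissipative_blocks <- function(state, model) {
  labels <- active_noise_blocks(state, model)
  lay <- state_layout(state)
  ntot <- length(pack_state(state))
  g <- model$grid
  blocks <- lapply(labels, function(lb) {
    fapply <- function(xi_flat) {
      xi <- block_xi_unflatten(lb, xi_flat, g)
      h <- block_factor_apply(lb, state, model, xi)
      out <- numeric(ntot)
      for (comp in names(h))
        if (!is.null(h[[comp]])) out[lay[[comp]]] <- as.vector(h[[comp]])
      out
    }
    b <- list(label = lb,
              components = block_components(lb),
              n_xi = block_xi_length(lb, g),
              factor_apply = fapply,
              dense_R = function() {
                n_xi <- block_xi_length(lb, g)
                vapply(seq_len(n_xi), function(k) {
                  e <- numeric(n_xi); e[k] <- 1; fapply(e)
                }, numeric(ntot))
              },
              dense_K = function() dense_block_K(lb, state, model, lay, ntot),
              apply = function(v) {
                R <- vapply(seq_len(block_xi_length(lb, g)), function(k) {
                  e <- numeric(block_xi_length(lb, g)); e[k] <- 1; fapply(e)
                }, numeric(ntot))
                R %*% crossprod(R, v)
              })
    class(b) <- "selm_dissipative_block"
    b
  })
  attr(blocks, "layout") <- lay
  blocks
}

# dense K^(j) from the operator formulas (independent of the factors)
dense_block_K <- function(label, state, model, lay, ntot) {
  p <- model$params; g <- model$grid
  K <- matrix(0, ntot, ntot)
  thC <- if (!is.null(state$thetaC)) state$thetaC else cell_field(g, p$theta0)
  switch(label,
    protein = {
      thP <- if (!is.null(state$thetaP)) state$thetaP else p$theta0
      K[lay$X, lay$X] <- diag(2) * thP / p$gamma_p
    },
    q = {
      D <- fv_divergence_matrix(g)
      thC_f <- cells_to_faces(thC, g)
      q_f <- cells_to_faces(pmax(state$q, 0), g)
      cf <- c(as.vector(thC_f$x * q_f$x), as.vector(thC_f$y * q_f$y)) /
        (p$gamma * p$c0 * g$dV)
      K[lay$q, lay$q] <- D %*% (cf * t(D))
    },
    conduction = {
      D <- fv_divergence_matrix(g)
      thC_f <- cells_to_faces(thC, g)
      cf <- p$kappaCC * c(as.vector(thC_f$x^2), as.vector(thC_f$y^2)) /
        (p$C_C^2 * g$dV)
      K[lay$thetaC, lay$thetaC] <- D %*% (cf * t(D))
    },
    PI = {
      r <- numeric(ntot)
      r[lay$thetaP] <- 1 / p$C_P
      r[lay$thetaI] <- -1 / p$C_I
      K <- p$kappaPI * state$thetaP * state$thetaI * tcrossprod(r)
    },
    IC = {
      kCI <- interface_conductivity(model, state$X)
      for (m in seq_along(kCI)) {
        r <- numeric(ntot)
        r[lay$thetaC[m]] <- 1 / (p$C_C * g$dV)
        r[lay$thetaI] <- -1 / p$C_I
        K <- K + kCI[m] * g$dV * state$thetaI * thC[m] * tcrossprod(r)
      }
    },
    ambient = {
      d <- p$kappa0 * as.vector(thC) * as.vector(model$ambient) /
        (p$C_C^2 * g$dV)
      K[lay$thetaC, lay$thetaC] <- diag(d, length(d))
    },
    stop("unknown block ", label))
  K
}

#' Dense total dissipative operator
#'
#' Sum of the embedded dense blocks `K = sum_j K^(j)` on the packed state
#' vector; the target of the increment-covariance (fluctuation-dissipation)
#' check is `2 kB K dt`.
#'
#' @inheritParams deterministic_drift
#' @export
dense_dissipative_operator <- function(state, model) {
  blocks <- dissipative_blocks(state, model)
  ntot <- length(pack_state(state))
  K <- matrix(0, ntot, ntot)
  for (b in blocks) K <- K + b$dense_K()
  attr(K, "layout") <- attr(blocks, "layout")
  K
}
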