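q_floor <- 1e-12

# Phi per cell for the model's potential (NULL if absent or no particle)
model_phi <- function(model, X) {
  if (is.null(X) || !isTRUE(model$potential$has_phi)) return(NULL)
  model$potential$phi_cells(model$grid, X)
}

#' Total energy of the system
#'
#' `E = Psi(X) + C_P thetaP + sum_m Phi(x_m; X) c0 q_m dV +
#'  sum_m C_C thetaC_m dV + C_I thetaI`.  Missing state components
#' contribute zero.
#'
#' @param state a [selm_state()].
#' @param model a [selm_model()].
#' @return Scalar energy.
#' @export
total_energy <- function(state, model) {
  p <- model$params; g <- model$grid
  E <- 0
  if (!is.null(state$X))
    E <- E + model$potential$psi(state$X, g)$value
  if (!is.null(state$thetaP)) E <- E + p$C_P * state$thetaP
  if (!is.null(state$thetaI)) E <- E + p$C_I * state$thetaI
  if (!is.null(state$thetaC)) E <- E + p$C_C * sum(state$thetaC) * g$dV
  phi <- model_phi(model, state$X)
  if (!is.null(phi) && !is.null(state$q))
    E <- E + p$c0 * sum(phi * state$q) * g$dV
  E
}

#' Total entropy of the system
#'
#' `S = C_P ln(thetaP) + C_I ln(thetaI) + sum_m [-c0 q_m ln(q_m) +
#'  C_C ln(thetaC_m)] dV`, with `0 ln 0 := 0` (cells below the floor
#' `1e-12` are clamped inside the logarithm).
#'
#' @inheritParams total_energy
#' @export
total_entropy <- function(state, model) {
  p <- model$params; g <- model$grid
  for (th in list(state$thetaP, state$thetaI))
    if (!is.null(th) && th <= 0) stop("nonpositive temperature")
  if (!is.null(state$thetaC) && any(state$thetaC <= 0))
    stop("nonpositive temperature")
  S <- 0
  if (!is.null(state$thetaP)) S <- S + p$C_P * log(state$thetaP)
  if (!is.null(state$thetaI)) S <- S + p$C_I * log(state$thetaI)
  if (!is.null(state$thetaC)) S <- S + p$C_C * sum(log(state$thetaC)) * g$dV
  if (!is.null(state$q)) {
    q <- state$q
    if (any(q < 0)) stop("negative q in entropy")
    qlq <- ifelse(q > 0, q * log(pmax(q, q_floor)), 0)
    S <- S - p$c0 * sum(qlq) * g$dV
  }
  S
}

#' Gradient of the entropy in each state component
#'
#' Blocks: `dS/dX = 0`; `dS/dq(x) = -c0 (1 + ln q(x))` (cells below the
#' floor are clamped); `dS/dthetaP = C_P / thetaP`; `dS/dthetaI = C_I /
#' thetaI`; `dS/dthetaC(x) = C_C / thetaC(x)`.  Field blocks are returned
#' as functional derivatives (per unit volume); multiply by `dV` for the
#' derivative with respect to a cell value.
#'
#' @inheritParams total_energy
#' @return List with components `X`, `q`, `thetaP`, `thetaI`, `thetaC`
#'   (NULL where the state lacks the component).
#' @export
entropy_gradient <- function(state, model) {
  p <- model$params
  out <- list(X = NULL, q = NULL, thetaP = NULL, thetaI = NULL, thetaC = NULL)
  if (!is.null(state$X)) out$X <- c(0, 0)
  if (!is.null(state$q))
    out$q <- -p$c0 * (1 + log(pmax(state$q, q_floor)))
  if (!is.null(state$thetaP)) out$thetaP <- p$C_P / state$thetaP
  if (!is.null(state$thetaI)) out$thetaI <- p$C_I / state$thetaI
  if (!is.null(state$thetaC)) out$thetaC <- p$C_C / state$thetaC
  out
}

#' Gradient of the energy in each state component
#'
#' Blocks: `dE/dX = grad Psi + sum_m grad_X Phi(x_m; X) c0 q_m dV`;
#' `dE/dq(x) = c0 Phi(x; X)`; `dE/dthetaP = C_P`; `dE/dthetaI = C_I`;
#' `dE/dthetaC(x) = C_C`.  Field blocks are functional derivatives, as in
#' [entropy_gradient()].
#'
#' @inheritParams total_energy
#' @export
energy_gradient <- function(state, model) {
  p <- model$params; g <- model$grid
  out <- list(X = NULL, q = NULL, thetaP = NULL, thetaI = NULL, thetaC = NULL)
  if (!is.null(state$X)) {
    gX <- model$potential$psi(state$X, g)$grad
    if (isTRUE(model$potential$has_phi) && !is.null(state$q)) {
      dphi <- model$potential$phi_gradX(g, state$X)
      gX <- gX + p$c0 * g$dV * c(sum(dphi$x * state$q), sum(dphi$y * state$q))
    }
    out$X <- gX
  }
  if (!is.null(state$q)) {
    phi <- model_phi(model, state$X)
    out$q <- if (is.null(phi)) cell_field(g, 0) else p$c0 * phi
  }
  if (!is.null(state$thetaP)) out$thetaP <- p$C_P
  if (!is.null(state$thetaI)) out$thetaI <- p$C_I
  if (!is.null(state$thetaC)) out$thetaC <- cell_field(g, p$C_C)
  out
}

#' Force on the protein
#'
#' `F_X = -dE/dX`: the negative `X`-block of [energy_gradient()].  For the
#' Gaussian well lattice this reproduces the closed-form restoring force
#' `-c2 ((X - X_i)/sigma0^2) exp(-|X - X_i|^2 / (2 sigma0^2))` summed over
#' wells; for the kernel coupling (default attractive sign) it points
#' toward higher interpolated concentration.
#'
#' @inheritParams total_energy
#' @return Length-2 force vector.
#' @export
protein_force <- function(state, model) {
  if (is.null(state$X)) stop("state has no particle")
  -energy_gradient(state, model)$X
}
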