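#' Deterministic drift of the coupled dynamics
#'
#' Assembles the noise-free right-hand side for the evolved components:
#'
#' * `X`: `M F_X` with `M = I / gamma_p` (the divergence-of-mobility term
#'   vanishes for a constant mobility).
#' * `q`: `div(kappa_f grad q) + div((q_f / gamma) grad Phi)` with the local
#'   diffusivity `kappa_f = thetaC_f / gamma` and all coefficients averaged
#'   to faces.
#' * `thetaC`: conduction `div(kappaCC grad thetaC) / C_C`, interface
#'   exchange `-(kappaCI(x; X)/C_C)(thetaC - thetaI)`, ambient relaxation
#'   `-(kappa0/C_C)(thetaC - theta_bath)`, and the viscous/mixing heating
#'   deposited by the species fluxes, evaluated per face as
#'   `c0 kappa_f (G Phi)(G q) + (c0 q_f / gamma) |G Phi|^2` and averaged
#'   back to cells.  These face-centered forms make the discrete energy
#'   budget close exactly: the heat deposited equals the potential energy
#'   released by the species fluxes.
#' * `thetaP`: `-(kappaPI/C_P)(thetaP - thetaI) + F M F / C_P`.
#' * `thetaI`: `(kappaPI/C_I)(thetaP - thetaI) +
#'   (1/C_I) sum_m kappaCI(x_m; X)(thetaC_m - thetaI) dV`.
#'
#' @param state a [selm_state()].
#' @param model a [selm_model()]; its `active` set controls which blocks
#'   are assembled (frozen components still feed the couplings).
#' @return State-shaped list of time derivatives (NULL for frozen/absent
#'   components).
#' @export
deterministic_drift <- function(state, model) {
  p <- model$params; g <- model$grid
  for (th in list(state$thetaP, state$thetaI))
    if (!is.null(th) && th <= 0) stop("nonpositive temperature in drift")
  if (!is.null(state$thetaC) && any(state$thetaC <= 0))
    stop("nonpositive temperature in drift")

  out <- list(X = NULL, q = NULL, thetaP = NULL, thetaI = NULL, thetaC = NULL)
  Fx <- if (!is.null(state$X)) protein_force(state, model) else NULL

  phi <- model_phi(model, state$X)
  have_q <- !is.null(state$q)
  thetaC_f <- if (!is.null(state$thetaC)) cells_to_faces(state$thetaC, g)
              else face_field(g, p$theta0, p$theta0)
  kappa_f <- list(x = thetaC_f$x / p$gamma, y = thetaC_f$y / p$gamma)

  Gphi <- q_f <- NULL
  if (have_q && !is.null(phi)) {
    Gphi <- fv_gradient(phi, g)
    q_f <- cells_to_faces(state$q, g)
  }

  if (model_evolves(model, "X") && !is.null(Fx)) out$X <- Fx / p$gamma_p

  if (model_evolves(model, "q") && have_q) {
    Gq <- fv_gradient(state$q, g)
    J <- list(x = kappa_f$x * Gq$x, y = kappa_f$y * Gq$y)
    if (!is.null(Gphi)) {
      J$x <- J$x + q_f$x / p$gamma * Gphi$x
      J$y <- J$y + q_f$y / p$gamma * Gphi$y
    }
    class(J) <- "selm_face_field"
    out$q <- fv_divergence(J, g)
  }

  kCI <- interface_conductivity(model, state$X)

  if (model_evolves(model, "thetaC") && !is.null(state$thetaC)) {
    GthC <- fv_gradient(state$thetaC, g)
    d <- fv_divergence(list(x = p$kappaCC * GthC$x, y = p$kappaCC * GthC$y),
                       g) / p$C_C
    if (!is.null(kCI) && !is.null(state$thetaI))
      d <- d - kCI / p$C_C * (state$thetaC - state$thetaI)
    if (p$kappa0 > 0)
      d <- d - p$kappa0 / p$C_C * (state$thetaC - model$ambient)
    if (!is.null(Gphi)) {
      Gq <- fv_gradient(state$q, g)
      h <- list(
        x = p$c0 * kappa_f$x * Gphi$x * Gq$x + p$c0 * q_f$x / p$gamma * Gphi$x^2,
        y = p$c0 * kappa_f$y * Gphi$y * Gq$y + p$c0 * q_f$y / p$gamma * Gphi$y^2)
      d <- d + faces_to_cells(h, g) / p$C_C
    }
    out$thetaC <- d
  }

  if (model_evolves(model, "thetaP") && !is.null(state$thetaP)) {
    d <- -p$kappaPI / p$C_P * (state$thetaP - state$thetaI)
    if (model_evolves(model, "X") && !is.null(Fx))
      d <- d + sum(Fx^2) / (p$gamma_p * p$C_P)
    out$thetaP <- d
    di <- p$kappaPI / p$C_I * (state$thetaP - state$thetaI)
    if (!is.null(kCI) && !is.null(state$thetaC))
      di <- di + sum(kCI * (state$thetaC - state$thetaI)) * g$dV / p$C_I
    out$thetaI <- di
  }
  out
}

# ---- fluctuation blocks -----------------------------------------------------

# which dissipative blocks generate noise for this model/state
active_noise_blocks <- function(state, model) {
  p <- model$params
  if (p$kB <= 0) return(character(0))
  b <- character(0)
  if (model_evolves(model, "X") && !is.null(state$X)) b <- c(b, "protein")
  if (model_evolves(model, "q") && !is.null(state$q)) b <- c(b, "q")
  if (model_evolves(model, "thetaC") && !is.null(state$thetaC)) {
    if (p$kappaCC > 0) b <- c(b, "conduction")
  }
  if (model_evolves(model, "thetaP") && !is.null(state$thetaP) &&
      p$kappaPI > 0) b <- c(b, "PI")
  if (model_evolves(model, "thetaP") && model_evolves(model, "thetaC") &&
      !is.null(state$thetaC) && p$kappaCI > 0 && !is.null(state$X) &&
      !is.null(model$interface_kernel)) b <- c(b, "IC")
  if (model_evolves(model, "thetaC") && !is.null(state$thetaC) &&
      p$kappa0 > 0) b <- c(b, "ambient")
  b
}

# one standard-normal variate set per active block, in canonical order
draw_noise_variates <- function(state, model) {
  g <- model$grid
  xi <- list()
  for (b in active_noise_blocks(state, model)) {
    xi[[b]] <- switch(b,
      protein    = stats::rnorm(2),
      q          = list(x = matrix(stats::rnorm(g$nx * g$ny), g$nx, g$ny),
                        y = matrix(stats::rnorm(g$nx * g$ny), g$nx, g$ny)),
      conduction = list(x = matrix(stats::rnorm(g$nx * g$ny), g$nx, g$ny),
                        y = matrix(stats::rnorm(g$nx * g$ny), g$nx, g$ny)),
      PI         = stats::rnorm(1),
      IC         = matrix(stats::rnorm(g$nx * g$ny), g$nx, g$ny),
      ambient    = matrix(stats::rnorm(g$nx * g$ny), g$nx, g$ny))
  }
  xi
}

# h_thm = sqrt(2 kB dt) sum_j R_j(state) xi_j, state-shaped
# (per-block factors live in noise.R alongside their dense oracles)
apply_noise_factors <- function(state, model, xi, dt) {
  h <- list(X = NULL, q = NULL, thetaP = NULL, thetaI = NULL, thetaC = NULL)
  if (length(xi) == 0) return(h)
  amp <- sqrt(2 * model$params$kB * dt)
  for (b in names(xi)) {
    hb <- block_factor_apply(b, state, model, xi[[b]])
    for (comp in names(hb)) {
      if (is.null(hb[[comp]])) next
      h[[comp]] <- if (is.null(h[[comp]])) amp * hb[[comp]]
                   else h[[comp]] + amp * hb[[comp]]
    }
  }
  h
}

#' Sample the thermal fluctuation increments
#'
#' Draws independent standard-normal variates per dissipative block and
#' returns the assembled state-shaped increments `h_thm = sqrt(2 kB dt)
#' R(Y) xi`, where `R` are the divergence-form factors with `R R^T = K`.
#' The conserved-field blocks (species, conduction) place the noise inside
#' a discrete divergence, so each draw sums to zero over the grid exactly.
#'
#' @inheritParams deterministic_drift
#' @param dt time step (the increments carry variance proportional to `dt`).
#' @return List with `h` (state-shaped increments) and `xi` (the raw
#'   variates, reusable for the corrector stage).
#' @export
sample_fluctuations <- function(state, model, dt) {
  xi <- draw_noise_variates(state, model)
  list(h = apply_noise_factors(state, model, xi, dt), xi = xi)
}

# ---- two-stage integrator ---------------------------------------------------

state_axpy <- function(state, a, dt, h = NULL, grid = NULL) {
  # state + a*dt + h, componentwise; wraps X periodically
  pick <- function(comp) {
    v <- state[[comp]]
    if (is.null(v)) return(NULL)
    if (!is.null(a[[comp]])) v <- v + a[[comp]] * dt
    if (!is.null(h) && !is.null(h[[comp]])) v <- v + h[[comp]]
    v
  }
  out <- list(X = pick("X"), q = pick("q"), thetaP = pick("thetaP"),
              thetaI = pick("thetaI"), thetaC = pick("thetaC"))
  if (!is.null(out$X) && !is.null(grid))
    out$X <- c(wrap_coord(out$X[1], grid$Lx), wrap_coord(out$X[2], grid$Ly))
  class(out) <- "selm_state"
  out
}

state_valid <- function(state) {
  ok <- TRUE
  for (th in list(state$thetaP, state$thetaI))
    if (!is.null(th)) ok <- ok && is.finite(th) && th > 0
  if (!is.null(state$thetaC))
    ok <- ok && all(is.finite(state$thetaC)) && all(state$thetaC > 0)
  if (!is.null(state$q)) {
    ok <- ok && all(is.finite(state$q))
    # multiplicative sqrt(q) noise can leave harmless sub-resolution
    # negatives near empty cells; reject only material negativity
    ok <- ok && min(state$q) > -1e-3 * max(state$q, 1e-12)
  }
  if (!is.null(state$X)) ok <- ok && all(is.finite(state$X))
  ok
}

#' One step of the two-stage stochastic integrator
#'
#' Euler-Heun predictor-corrector: the predictor advances with the drift
#' and noise coefficients at the current state; the corrector averages the
#' drift and the noise coefficients at the current and predicted states,
#' reusing the *same* Wiener increments in both stages.  This approximates
#' the Stratonovich formulation, so no explicit divergence-of-`K` drift is
#' added.  With state-independent noise amplitude the two stages coincide
#' with Euler-Maruyama for the noise.
#'
#' A step whose corrector violates temperature positivity (or materially
#' negative `q`) is rejected and retried as two half-steps with fresh
#' draws, up to 5 halvings, then a hard error is raised.
#'
#' @inheritParams sample_fluctuations
#' @param noise logical; `FALSE` integrates the deterministic drift only.
#' @param max_halvings retry depth for rejected steps.
#' @return The advanced `selm_state`.
#' @export
selm_step <- function(state, dt, model, noise = TRUE, max_halvings = 5) {
  a1 <- deterministic_drift(state, model)
  if (noise) {
    s <- sample_fluctuations(state, model, dt)
    h1 <- s$h; xi <- s$xi
  } else {
    h1 <- NULL; xi <- list()
  }
  pred <- state_axpy(state, a1, dt, h1, model$grid)
  new <- NULL
  if (state_valid(pred)) {
    a2 <- deterministic_drift(pred, model)
    h2 <- if (noise) apply_noise_factors(pred, model, xi, dt) else NULL
    abar <- mapply(function(u, v) if (is.null(u)) NULL else (u + v) / 2,
                   a1, a2, SIMPLIFY = FALSE)
    hbar <- if (noise)
      mapply(function(u, v) if (is.null(u)) NULL else (u + v) / 2,
             h1, h2, SIMPLIFY = FALSE) else NULL
    new <- state_axpy(state, abar, dt, hbar, model$grid)
  }
  if (is.null(new) || !state_valid(new)) {
    if (max_halvings <= 0)
      stop("selm_step: positivity violation persists after 5 halvings")
    half <- selm_step(state, dt / 2, model, noise, max_halvings - 1)
    return(selm_step(half, dt / 2, model, noise, max_halvings - 1))
  }
  new
}
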