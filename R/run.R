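# flatten a selm_model into the list consumed by the compiled stepper
cpp_model_spec <- function(model, noise = TRUE) {
  p <- model$params; g <- model$grid; pot <- model$potential
  spec <- list(nx = g$nx, ny = g$ny, dx = g$dx,
               kB = p$kB, c0 = p$c0, gamma = p$gamma, gamma_p = p$gamma_p,
               kappaPI = p$kappaPI, kappaCI = p$kappaCI,
               kappaCC = p$kappaCC, kappa0 = p$kappa0,
               C_P = p$C_P, C_C = p$C_C, C_I = p$C_I, theta0 = p$theta0,
               evX = model_evolves(model, "X"),
               evQ = model_evolves(model, "q"),
               evT = model_evolves(model, "thetaP"),
               evC = model_evolves(model, "thetaC"),
               pot_type = 0L, pot_k = 0, pot_cx = 0, pot_cy = 0,
               pot_k1 = 0, pot_sigma0 = 1, pot_rcut = 0, pot_sign = -1,
               pot_c2 = 0, pot_sigma0w = 1,
               well_x = numeric(0), well_y = numeric(0),
               has_ifk = FALSE, ifk_sigma0 = 1, ifk_rcut = 0,
               bath = as.vector(model$ambient), noise = isTRUE(noise))
  spec[["pot_type"]] <- switch(pot$kind, none = 0L, harmonic = 1L,
                               kernel = 2L, wells = 3L,
                               stop("unsupported potential for compiled run"))
  if (pot$kind == "harmonic") {
    spec$pot_k <- pot$k; spec$pot_cx <- pot$center[1]
    spec$pot_cy <- pot$center[2]
  } else if (pot$kind == "kernel") {
    if (pot$kernel$kind != "gaussian")
      stop("compiled run supports gaussian coupling kernels")
    spec$pot_k1 <- pot$kernel$k1; spec$pot_sigma0 <- pot$kernel$sigma0
    spec$pot_rcut <- pot$kernel$r_cut; spec$pot_sign <- pot$sign
  } else if (pot$kind == "wells") {
    spec$pot_c2 <- pot$c2; spec$pot_sigma0w <- pot$sigma0
    spec$well_x <- pot$centers[, 1]; spec$well_y <- pot$centers[, 2]
  }
  if (!is.null(model$interface_kernel) && p$kappaCI > 0) {
    ik <- model$interface_kernel
    if (ik$kind != "gaussian")
      stop("compiled run supports gaussian interface kernels")
    spec$has_ifk <- TRUE
    spec$ifk_sigma0 <- ik$sigma0; spec$ifk_rcut <- ik$r_cut
  }
  spec
}

#' Integrate a trajectory of the coupled system
#'
#' Advances the state with the two-stage stochastic integrator for
#' `n_steps` steps of size `dt`, using the compiled stepping loop.  The
#' compiled loop reproduces the R-level [selm_step()] draw-for-draw from
#' the same RNG state.
#'
#' @param state initial [selm_state()].
#' @param model a [selm_model()].
#' @param dt time step.
#' @param n_steps number of steps.
#' @param record_stride particle/temperature recording interval in steps
#'   (0 = record nothing).
#' @param field_stride field snapshot interval in steps (0 = none).
#' @param escape radius/center stopping rule: `NULL`, or
#'   `list(center = c(x, y), r0 = radius)`; the run stops at the first
#'   step whose minimum-image distance from the center reaches `r0`.
#' @param noise logical; `FALSE` integrates the deterministic drift only.
#' @return Object of class `selm_trajectory`: list with `particle` (data
#'   frame of recorded `t`, `X1`, `X2`, `thetaP`, `thetaI`), `fields`
#'   (list of snapshot arrays and times), `final` state, `escape_time`
#'   (NA if no stopping rule hit), `time` reached, and the rejection count.
#' @export
run_selm <- function(state, model, dt, n_steps, record_stride = 0L,
                     field_stride = 0L, escape = NULL, noise = TRUE) {
  spec <- cpp_model_spec(model, noise)
  s0 <- list(X = state$X, q = if (is.null(state$q)) NULL else as.vector(state$q),
             thetaP = state$thetaP, thetaI = state$thetaI,
             thetaC = if (is.null(state$thetaC)) NULL else as.vector(state$thetaC))
  r0 <- if (is.null(escape)) -1 else escape$r0
  ctr <- if (is.null(escape)) c(0, 0) else escape$center
  out <- cpp_run_selm(spec, s0, dt, as.integer(n_steps),
                      as.integer(record_stride), as.integer(field_stride),
                      r0, ctr)
  g <- model$grid
  fin <- out$final
  final <- selm_state(g,
    X = fin$X,
    q = if (is.null(fin$q)) NULL else matrix(fin$q, g$nx, g$ny),
    thetaP = fin$thetaP, thetaI = fin$thetaI,
    thetaC = if (is.null(fin$thetaC)) NULL else matrix(fin$thetaC, g$nx, g$ny))
  nr <- out$n_recorded
  particle <- data.frame(t = out$t[seq_len(nr)],
                         X1 = out$X[seq_len(nr), 1],
                         X2 = out$X[seq_len(nr), 2],
                         thetaP = out$thetaP[seq_len(nr)],
                         thetaI = out$thetaI[seq_len(nr)])
  nf <- out$n_field_recorded
  fields <- list(t = out$t_fields[seq_len(nf)],
                 q = if (ncol(out$q_fields) > 0)
                   out$q_fields[, seq_len(nf), drop = FALSE] else NULL,
                 thetaC = if (ncol(out$thetaC_fields) > 0)
                   out$thetaC_fields[, seq_len(nf), drop = FALSE] else NULL)
  res <- list(particle = particle, fields = fields, final = final,
              escape_time = out$escape_time, time = out$time,
              n_rejections = out$n_rejections)
  class(res) <- "selm_trajectory"
  res
}

#' @export
print.selm_trajectory <- function(x, ...) {
  cat(sprintf("<selm_trajectory> t = %g, %d particle records, %d field snapshots",
              x$time, nrow(x$particle), length(x$fields$t)))
  if (!is.na(x$escape_time)) cat(sprintf(", escaped at t = %g", x$escape_time))
  if (x$n_rejections > 0) cat(sprintf(", %d rejected steps", x$n_rejections))
  cat("\n")
  invisible(x)
}
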