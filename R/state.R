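#' System state
#'
#' The full state advanced by the integrator: particle position `X`, the
#' dimensionless species distribution `q` (concentration is `c0 * q`),
#' scalar protein and interface temperatures `thetaP`, `thetaI`, and the
#' membrane temperature cell field `thetaC`.  Components that a given model
#' does not use may be `NULL` (e.g. `q` in the escape study, `X` in the
#' sensing study).
#'
#' @param X particle position (length-2), or `NULL`.
#' @param q species distribution cell field (matrix), or `NULL`.
#' @param thetaP,thetaI scalar temperatures (> 0).
#' @param thetaC membrane temperature cell field (> 0 cellwise).
#' @param grid the [selm_grid()] the fields live on.
#' @return Object of class `selm_state`.
#' @export
selm_state <- function(grid, X = NULL, q = NULL,
                       thetaP = NULL, thetaI = NULL, thetaC = NULL) {
  if (!is.null(X)) {
    stopifnot(length(X) == 2, all(is.finite(X)))
    X <- c(wrap_coord(X[1], grid$Lx), wrap_coord(X[2], grid$Ly))
  }
  if (!is.null(q)) q <- cell_field(grid, q)
  if (!is.null(thetaC)) {
    thetaC <- cell_field(grid, thetaC)
    if (any(thetaC <= 0)) stop("thetaC must be positive cellwise")
  }
  for (th in list(thetaP, thetaI))
    if (!is.null(th) && (!is.finite(th) || th <= 0))
      stop("scalar temperatures must be positive")
  s <- list(X = X, q = q, thetaP = thetaP, thetaI = thetaI, thetaC = thetaC)
  class(s) <- "selm_state"
  s
}

#' @export
print.selm_state <- function(x, ...) {
  cat("<selm_state>")
  if (!is.null(x$X)) cat(sprintf(" X = (%.4g, %.4g)", x$X[1], x$X[2]))
  if (!is.null(x$thetaP)) cat(sprintf(" thetaP = %.4g", x$thetaP))
  if (!is.null(x$thetaI)) cat(sprintf(" thetaI = %.4g", x$thetaI))
  if (!is.null(x$q)) cat(sprintf(" | q: [%.3g, %.3g]", min(x$q), max(x$q)))
  if (!is.null(x$thetaC))
    cat(sprintf(" | thetaC: [%.3g, %.3g]", min(x$thetaC), max(x$thetaC)))
  cat("\n")
  invisible(x)
}

#' Model definition
#'
#' Bundles grid, physical parameters, the potential acting on the protein,
#' the interface coupling kernel, the ambient bath, and which state
#' components the dynamics evolve.  Frozen components still enter the
#' couplings (e.g. a frozen `thetaC` still sets the species diffusivity).
#'
#' @param grid a [selm_grid()].
#' @param params a [selm_params()].
#' @param potential a potential object (see [potential_none()] and
#'   friends) providing `Psi` and the chemical potential `Phi`.
#' @param interface_kernel [kernel_spec()] for the interface--membrane
#'   conductivity footprint `kappaCI(x; X) = kappaCI * eta_unit(x - X)`
#'   (unit amplitude); `NULL` disables the interface--membrane exchange.
#' @param ambient bath temperature: `NULL` (defaults to uniform `theta0`
#'   when `kappa0 > 0`), a scalar, or a cell field (e.g. the sustained
#'   heating profile of the escape study).
#' @param active character vector naming the evolved components, a subset
#'   of `c("X", "q", "thetaP", "thetaI", "thetaC")`.  `thetaP` and
#'   `thetaI` are evolved together.
#' @return Object of class `selm_model`.
#' @export
selm_model <- function(grid, params, potential = potential_none(),
                       interface_kernel = NULL, ambient = NULL,
                       active = c("X", "q", "thetaP", "thetaI", "thetaC")) {
  stopifnot(inherits(grid, "selm_grid"), inherits(params, "selm_params"))
  active <- match.arg(active, several.ok = TRUE)
  if (("thetaP" %in% active) != ("thetaI" %in% active))
    stop("thetaP and thetaI are evolved together")
  if (is.null(ambient)) ambient <- params$theta0
  if (length(ambient) == 1) ambient <- cell_field(grid, ambient)
  if (!is.null(interface_kernel)) check_kernel_domain(interface_kernel, grid)
  m <- list(grid = grid, params = params, potential = potential,
            interface_kernel = interface_kernel,
            ambient = cell_field(grid, ambient), active = active)
  class(m) <- "selm_model"
  m
}

model_evolves <- function(model, comp) comp %in% model$active

# interface conductivity footprint kappaCI(x; X) as a cell field (0 if off)
interface_conductivity <- function(model, X) {
  p <- model$params
  if (p$kappaCI <= 0 || is.null(model$interface_kernel) || is.null(X))
    return(NULL)
  p$kappaCI * kernel_on_grid(X, model$interface_kernel, model$grid)
}
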