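config_sections <- c("grid", "params", "integrator", "study", "scenario",
                     "output")

#' Load a full study configuration preset
#'
#' Returns the complete configuration document for one of the three
#' tabulated studies: the physical parameter set, the grid, the tabulated
#' time step, and the study-specific constants (kernel widths, initial
#' positions, well strength, filter constants).
#'
#' @param name `"table1"`, `"table2"`, or `"table3"`.
#' @return Nested list of class `selm_config` with sections `grid`,
#'   `params`, `integrator`, `study`.
#' @export
load_preset <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  p <- selm_preset(name)
  cfg <- list(
    grid = attr(p, "grid"),
    params = unclass(p)[setdiff(names(p), "gamma")],
    integrator = list(dt = attr(p, "dt")),
    study = attr(p, "study"),
    scenario = switch(name, table1 = "positioning", table2 = "sensing",
                      table3 = "escape"))
  class(cfg) <- "selm_config"
  cfg
}

#' Validate a configuration document
#'
#' Rejects unknown sections/keys and re-checks the grid and physical
#' parameter invariants (positivity, minimum grid size) by constructing
#' the corresponding objects.
#'
#' @param cfg a nested configuration list.
#' @return The validated config (invisibly), or an error.
#' @export
validate_selm_config <- function(cfg) {
  bad <- setdiff(names(cfg), config_sections)
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$grid))
    do.call(selm_grid, cfg$grid[intersect(names(cfg$grid),
                                          c("nx", "ny", "dx"))])
  if (!is.null(cfg$params)) {
    known <- names(formals(selm_params))
    bad <- setdiff(names(cfg$params), known)
    if (length(bad)) stop("unknown params keys: ", paste(bad, collapse = ", "))
    do.call(selm_params, cfg$params)
  }
  if (!is.null(cfg$integrator$dt) && cfg$integrator$dt <= 0)
    stop("integrator dt must be positive")
  invisible(cfg)
}

#' Read and write configuration documents as YAML
#'
#' The YAML form is the on-disk interchange for experiment configs; every
#' run directory gets an echo of the resolved configuration.  Reading
#' re-validates all invariants.
#'
#' @param path file path.
#' @param cfg configuration list.
#' @name config_io
#' @export
read_selm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_selm_config(cfg)
  class(cfg) <- "selm_config"
  cfg
}

#' @rdname config_io
#' @export
write_selm_config <- function(cfg, path) {
  # 17 significant digits so doubles round-trip bit-exactly
  writeLines(yaml::as.yaml(unclass(cfg), precision = 17), path)
  invisible(path)
}

#' Reference scales for dimensional reporting
#'
#' The characteristic scales that map the non-dimensional model quantities
#' to physical units: length 10 nm, mass 50 kDa, time 1 microsecond, and
#' thermal energy `kB * T_ref = 4.1e-21` J.  Derived scales (diffusivity,
#' rate, velocity) follow from these.
#'
#' @param length_nm,mass_kDa,time_us,energy_J the four base scales.
#' @return Named list of scales with unit labels.
#' @export
reference_scales <- function(length_nm = 10, mass_kDa = 50, time_us = 1,
                             energy_J = 4.1e-21) {
  stopifnot(length_nm > 0, mass_kDa > 0, time_us > 0, energy_J > 0)
  list(
    length      = list(scale = length_nm, unit = "nm"),
    mass        = list(scale = mass_kDa, unit = "kDa"),
    time        = list(scale = time_us, unit = "us"),
    energy      = list(scale = energy_J, unit = "J"),
    temperature = list(scale = 1, unit = "T_ref"),
    diffusivity = list(scale = length_nm^2 / time_us, unit = "nm^2/us"),
    rate        = list(scale = 1 / time_us, unit = "1/us"),
    velocity    = list(scale = length_nm / time_us, unit = "nm/us"))
}

#' Convert non-dimensional quantities to dimensional units
#'
#' For a non-dimensional value `z` of a given kind, the dimensional value
#' is `z * Z_ref` with `Z_ref` the corresponding reference scale; the
#' inverse mapping divides, so the round trip is the identity.
#'
#' @param value numeric vector of non-dimensional values.
#' @param kind character vector of quantity kinds (recycled), each one of
#'   `names(reference_scales())`.
#' @param name optional labels.
#' @param scales a [reference_scales()] list.
#' @return Data frame with the non-dimensional value, the dimensional
#'   value, and its unit.
#' @export
nondimensional_report <- function(value, kind, name = NULL,
                                  scales = reference_scales()) {
  kind <- rep_len(kind, length(value))
  bad <- setdiff(unique(kind), names(scales))
  if (length(bad)) stop("no reference scale for: ", paste(bad, collapse = ", "))
  sc <- vapply(kind, function(k) scales[[k]]$scale, numeric(1))
  un <- vapply(kind, function(k) scales[[k]]$unit, character(1))
  data.frame(name = if (is.null(name)) as.character(seq_along(value)) else name,
             kind = kind, value = value, dimensional = value * sc, unit = un,
             row.names = NULL)
}
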