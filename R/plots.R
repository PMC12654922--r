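need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package")
}

#' Plot a cell field as a raster
#'
#' @param f cell field (matrix) on `grid`.
#' @param grid a [selm_grid()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_cell_field <- function(f, grid, title = NULL) {
  need_ggplot()
  d <- expand.grid(x = grid$xc, y = grid$yc)
  d$value <- as.vector(f)
  ggplot2::ggplot(d, ggplot2::aes(x = x, y = y,
                                  fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = "x", y = "y")
}

#' Plot scenario results
#'
#' Quick-look figures for the three study outputs: scaled final position
#' against diffusivity (positioning), the filtered sensor profile with
#' replicate error bars per amplitude (sensing), and mean escape time
#' against heating strength (escape).
#'
#' @param res output of the corresponding scenario runner (for
#'   [plot_escape()], of [summarize_escape()]).
#' @return A ggplot object.
#' @name scenario_plots
NULL

#' @rdname scenario_plots
#' @export
plot_positioning <- function(res) {
  need_ggplot()
  ggplot2::ggplot(res, ggplot2::aes(x = factor(kappa_bar),
                                    y = y)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~gamma_p, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "species diffusivity", y = "scaled final position y")
}

#' @rdname scenario_plots
#' @export
plot_sensing <- function(res) {
  need_ggplot()
  ggplot2::ggplot(res, ggplot2::aes(x = x, y = Ibar_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = Ibar_mean - Ibar_sd,
      ymax = Ibar_mean + Ibar_sd)) +
    ggplot2::facet_wrap(~a0, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sensor position x", y = "filtered signal")
}

#' @rdname scenario_plots
#' @export
plot_escape <- function(res) {
  need_ggplot()
  ggplot2::ggplot(res, ggplot2::aes(x = c3, y = mean_escape)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = mean_escape - se_escape,
      ymax = mean_escape + se_escape)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~c2, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "heating strength c3", y = "mean escape time")
}
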