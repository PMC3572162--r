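# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @method tidy rdf_result
#' @export
tidy.rdf_result <- function(x, ...) {
  tibble::tibble(r = x$r, g = x$g, count = x$count)
}

#' @method glance rdf_result
#' @export
glance.rdf_result <- function(x, ...) {
  peak <- which.max(x$g)
  tibble::tibble(n_bins = nrow(x), n_frames = attr(x, "n_frames"),
                 r_peak = x$r[peak], g_peak = x$g[peak])
}

#' @method autoplot rdf_result
#' @export
autoplot.rdf_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = r, y = g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "r (nm)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' @method tidy pr_curve
#' @export
tidy.pr_curve <- function(x, ...) tibble::tibble(r = x$r, p = x$p)

#' Summary statistics of a pair-distance curve
#'
#' @param x a `pr_curve`.
#' @param ... unused.
#' @return one-row tibble with `Rg` and `Dmax` (Angstrom).
#' @method glance pr_curve
#' @export
glance.pr_curve <- function(x, ...) {
  tibble::tibble(Rg = attr(x, "Rg"), Dmax = attr(x, "Dmax"),
                 bin_width = attr(x, "bin_width"))
}

#' @method autoplot pr_curve
#' @export
autoplot.pr_curve <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = r, y = p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = g$Dmax, linetype = "dotted") +
    ggplot2::labs(x = "r (Å)", y = "P(r)",
                  subtitle = sprintf("Rg = %.1f Å, Dmax = %.0f Å",
                                     g$Rg, g$Dmax)) +
    ggplot2::theme_minimal()
}

#' @method tidy cg_trajectory
#' @export
tidy.cg_trajectory <- function(x, ...) kinetic_temperature(x)

#' @method glance cg_trajectory
#' @export
glance.cg_trajectory <- function(x, ...) {
  kt <- kinetic_temperature(x)
  tibble::tibble(n_frames = length(x$frames), n_beads = nrow(x$frames[[1]]),
                 box_edge = x$box_edge,
                 mean_kT = mean(kt$kT_inst),
                 mean_potential = mean(x$potential))
}

#' @method autoplot cg_trajectory
#' @export
autoplot.cg_trajectory <- function(object, ...) {
  kt <- kinetic_temperature(object)
  d <- tidyr::pivot_longer(kt, c("potential", "kT_inst"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = step, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "MD step", y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot sdf_grid
#' @export
autoplot.sdf_grid <- function(object, slice = NULL, ...) {
  d <- dim(object$density)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = object$axes, y = object$axes)
  df$density <- as.vector(object$density[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = density)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x' (Å)", y = "y' (Å)",
                  subtitle = sprintf("z' slice %d (%.0f Å)", slice,
                                     object$axes[slice])) +
    ggplot2::theme_minimal()
}
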