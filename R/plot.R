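# ggplot2 views of scan and pathway results.

#' @exportS3Method ggplot2::autoplot
autoplot.nc_shape_scan <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- sprintf("[%g %g %g]", df$dx, df$dy, df$dz)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$rank),
                                   y = .data$energy_per_atom)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ellipsoid axes Dx Dy Dz (nm)",
                  y = "avg potential energy per atom (eV)",
                  title = "Fixed-volume shape scan (most stable first)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.nc_rotation_scan <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$angle, y = .data$energy_per_atom)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rotation angle (degrees)",
                  y = "avg potential energy per atom (eV)",
                  title = "Rotation scan at fixed ellipsoid axes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.nc_growth_path <- function(object, ...) {
  path <- object$path
  path$label <- sprintf("[%g %g %g]", path$dx, path$dy, path$dz)
  p <- ggplot2::ggplot(path, ggplot2::aes(x = .data$step,
                                          y = .data$energy_per_atom))
  if (nrow(object$candidates) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$candidates,
      ggplot2::aes(x = .data$step, y = .data$energy_per_atom),
      colour = "grey60", shape = 1, na.rm = TRUE)
  }
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "growth step",
                  y = "avg potential energy per atom (eV)",
                  title = "Greedy crystal-growth pathway",
                  subtitle = "grey circles: scored candidates; red: chosen route") +
    ggplot2::theme_minimal()
}
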