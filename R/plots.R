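#' @export
autoplot.contact_histogram <- function(object, ...) {
  d <- as_tibble(object)
  d$bin <- factor(d$bin, levels = d$bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "lipid component", y = "occurrence (%)",
                  title = "Drug-lipid contact occurrence by component") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ir_spectrum <- function(object, eps_threshold = 200, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, xend = .data$frequency,
                                  y = 0, yend = .data$epsilon)) +
    ggplot2::geom_segment() +
    ggplot2::geom_hline(yintercept = eps_threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = expression(frequency ~ (cm^-1)),
                  y = expression(epsilon ~ (M^-1 ~ cm^-1)),
                  title = attr(object, "name")) +
    ggplot2::theme_minimal()
}

#' Depth trace of a trajectory
#'
#' Solute center-of-mass depth against time, with the membrane surface
#' (proximal phosphate plane) and the detected insertion time marked.
#'
#' @param traj A `mem_trajectory`.
#' @param surface_z Surface line to draw (default: trajectory's phosphate
#'   plane).
#' @return A ggplot object.
#' @export
plot_insertion_depth <- function(traj, surface_z = NULL) {
  surface_z <- surface_z %||% traj$meta$surface_z
  p <- ggplot2::ggplot(drug_depth(traj),
                       ggplot2::aes(x = .data$time_ns, y = .data$z)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "time (ns)", y = "z (Å, bilayer center at 0)",
                  title = "Solute depth above the bilayer") +
    ggplot2::theme_minimal()
  if (!is.null(surface_z)) {
    p <- p + ggplot2::geom_hline(yintercept = surface_z, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Tilt-angle histogram plot
#'
#' @param series Angle series (tibble with `angle_deg` or numeric vector).
#' @param bin_width Bin width in degrees (must divide 180).
#' @return A ggplot object.
#' @export
plot_angle_histogram <- function(series, bin_width = 10) {
  h <- angle_histogram(series, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.9, fill = "steelblue") +
    ggplot2::labs(x = "angle to bilayer normal (deg)", y = "frames") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.study_report <- function(object, ...) {
  d <- object$kin
  if (nrow(d) == 0) abort("report has no kinetics results to plot")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$analogue, y = .data$K_in,
                                  fill = .data$lipid)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression(K["in"] ~ (M^-1 ~ s^-1)),
                  title = "Insertion association constants") +
    ggplot2::theme_minimal()
}
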