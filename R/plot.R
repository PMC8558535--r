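#' Plot a surface-distance hydration profile
#'
#' @param object A `wat_profile` from [surface_distance_profile()].
#' @param ... Unused.
#' @return A ggplot: waters per protein vs distance from the protein
#'   surface, one line per atom class.
#' @export
autoplot.wat_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_center, y = .data$count,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance from protein surface (Å)",
                  y = "Waters per protein",
                  colour = "Class") +
    ggplot2::theme_minimal()
}

#' Plot a distance-angle hydrogen-bond geometry map
#'
#' @param object A `wat_geometry_map` from [geometry_map()] or
#'   [crystal_geometry_map()].
#' @param ... Unused.
#' @return A ggplot heat map of counts over (r, theta).
#' @export
autoplot.wat_geometry_map <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r_center, y = .data$theta_center,
                               fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "r, H...O distance (Å)",
                  y = expression(theta ~ "(degrees)"),
                  fill = "Count",
                  title = attr(object, "pair_class")) +
    ggplot2::theme_minimal()
}

#' Plot a residue-residue contact map
#'
#' @param object A `wat_contact_map` from [contact_map()].
#' @param ... Unused.
#' @return A ggplot tile map of residue contacts.
#' @export
autoplot.wat_contact_map <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(tibble::as_tibble(object), .data$contact),
                  ggplot2::aes(x = .data$resid_a, y = .data$resid_b)) +
    ggplot2::geom_tile() +
    ggplot2::labs(
      x = paste("Residue, chain", attr(object, "chain_a")),
      y = paste("Residue, chain", attr(object, "chain_b"))) +
    ggplot2::theme_minimal()
}

#' Plot hydration-level trend curves
#'
#' @param trends Output of [peak_trends()].
#' @return A ggplot of waters per protein at the probe distances vs h.
#' @export
plot_peak_trends <- function(trends) {
  ggplot2::ggplot(trends,
                  ggplot2::aes(x = .data$h, y = .data$value,
                               colour = .data$class,
                               linetype = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Hydration level h (g water / g protein)",
                  y = "Waters per protein at probe distance",
                  colour = "Class", linetype = "Probe") +
    ggplot2::theme_minimal()
}
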