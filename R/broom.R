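#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a geometry map into a long tibble
#'
#' @param x A `wat_geometry_map`.
#' @param ... Unused.
#' @return A plain tibble of `r_center`, `theta_center`, `count`.
#' @export
tidy.wat_geometry_map <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("r_center", "theta_center", "count")])
}

#' One-row summary of a geometry map
#'
#' @param x A `wat_geometry_map`.
#' @param ... Unused.
#' @return Tibble with the peak location ([map_peak()]), the total scored
#'   pair count, the in-range count and the spill count.
#' @export
glance.wat_geometry_map <- function(x, ...) {
  pk <- map_peak(x)
  tibble::tibble(peak_r = pk$r, peak_theta = pk$theta,
                 peak_count = pk$count,
                 n_scored = attr(x, "n_scored"),
                 n_binned = sum(x$count),
                 spill = attr(x, "spill"),
                 pair_class = attr(x, "pair_class"))
}

#' Tidy a hydration profile
#'
#' @param x A `wat_profile`.
#' @param ... Unused.
#' @return The profile as a plain tibble.
#' @export
tidy.wat_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a bulk-water Monte Carlo trajectory
#'
#' @param x A `wat_trajectory` returned by [mc_bulk_water()].
#' @param ... Unused.
#' @return Tibble with frame/molecule counts, mean production energy,
#'   acceptance rate and the equilibration plateau flag.
#' @export
glance.wat_trajectory <- function(x, ...) {
  en <- attr(x, "energy")
  tibble::tibble(
    n_frames = n_frames(x),
    n_waters = nrow(x$topology) / 3,
    mean_energy = if (is.null(en)) NA_real_ else {
      mean(utils::tail(en, max(1, length(en) %/% 4)))
    },
    acceptance = attr(x, "acceptance") %||% NA_real_,
    equilibrated = attr(x, "equilibrated") %||% NA)
}
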