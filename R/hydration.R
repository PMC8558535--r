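#' Surface-distance hydration profile
#'
#' For every water oxygen in every frame, the distance to the protein
#' surface is the minimum over all protein atoms (hydrogens included)
#' under the minimum image; class profiles (`main_chain`,
#' `side_chain_hydrophilic`, `side_chain_hydrophobic`) use the minimum
#' over atoms of that class only, so each water oxygen contributes once
#' per class histogram. Counts are averaged over frames and divided by
#' the number of protein chains (copies), giving waters per protein.
#'
#' @param traj A `wat_trajectory` (or single structure) containing protein
#'   and water.
#' @param bin_width Histogram bin width (A).
#' @param r_max Largest surface distance histogrammed (A).
#' @param h Optional hydration level recorded on the output.
#' @return A tibble of class `wat_profile` in long format: `class`,
#'   `bin_lo`, `bin_hi`, `bin_center`, `count` (mean waters per protein
#'   per frame), `h`.
#' @export
surface_distance_profile <- function(traj, bin_width = 0.1, r_max = 6,
                                     h = NA_real_) {
  if (r_max <= 0) stop("r_max must be positive", call. = FALSE)
  stopifnot(bin_width > 0)
  traj <- as_trajectory(traj)
  top <- traj$topology
  if (!"atom_class" %in% names(top)) {
    top <- suppressWarnings(classify_atoms(top))
  }
  prot_classes <- c("main_chain", "side_chain_hydrophilic",
                    "side_chain_hydrophobic")
  is_prot <- top$atom_class %in% prot_classes
  if (!any(is_prot)) stop("no protein atoms present", call. = FALSE)
  is_wo <- top$atom_class == "water" & toupper(top$element) == "O"
  n_chains <- dplyr::n_distinct(top$chain[is_prot])
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  sets <- c(stats::setNames(as.list(prot_classes), prot_classes),
            list(whole_surface = prot_classes))
  acc <- lapply(sets, function(x) numeric(length(edges) - 1L))
  for (i in seq_len(n_frames(traj))) {
    xyz <- traj$coords[[i]]
    box <- traj$boxes[[i]]
    wo <- xyz[is_wo, , drop = FALSE]
    if (nrow(wo) == 0) next
    for (nm in names(sets)) {
      ref <- xyz[top$atom_class %in% sets[[nm]], , drop = FALSE]
      if (nrow(ref) == 0) next
      dmin <- apply(cross_dist(wo, ref, box), 1, min)
      dmin <- dmin[dmin < max(edges)]
      # half-open bins with a snap tolerance, so a distance constructed
      # exactly on an edge lands in the upper bin despite sqrt rounding
      acc[[nm]] <- acc[[nm]] +
        as.numeric(table(cut(dmin + 1e-9, edges, right = FALSE,
                             include.lowest = FALSE)))
    }
  }
  nf <- n_frames(traj)
  out <- purrr::map_dfr(names(acc), function(nm) {
    tibble::tibble(
      class = nm,
      bin_lo = edges[-length(edges)], bin_hi = edges[-1],
      bin_center = (edges[-length(edges)] + edges[-1]) / 2,
      count = acc[[nm]] / nf / n_chains, h = h)
  })
  class(out) <- c("wat_profile", class(out))
  out
}

default_r_edges <- function() seq(1.2, 4.0, by = 0.1)
default_theta_edges <- function() seq(0, 90, by = 5)

#' 2D distance-angle hydrogen-bond geometry map
#'
#' Accumulates (r, theta) for all scored donor-hydrogen / acceptor pairs
#' of the requested class over the frames of a trajectory, where r is the
#' hydrogen-to-acceptor-oxygen distance and theta the deviation from
#' linearity. Scoring is wider than the bond criterion: no angle gate is
#' applied, so close but non-bonded geometries (hydrogens pointing away
#' from a first-shell neighbour; large r, large theta) populate the map
#' as well. With the default `gate = "distance"` a pair is scored when
#' the donor-heavy to acceptor distance is below `d_gate` (the same
#' distance gate as the bond criterion); `gate = "hydrogen"` instead
#' scores every pair with the H-to-acceptor distance at most `r_gate`.
#' Geometries outside the bin ranges are dropped and counted in the
#' `spill` attribute.
#'
#' @param traj A `wat_trajectory` or single structure.
#' @param pair_class `"water_water"` or `"water_protein"`.
#' @param r_edges,theta_edges Bin edges (defaults 1.2--4.0 A by 0.1 and
#'   0--90 degrees by 5).
#' @param gate Scoring gate type: `"distance"` (donor-acceptor
#'   heavy-atom distance, the default) or `"hydrogen"` (H-acceptor
#'   distance).
#' @param d_gate Heavy-atom distance gate (A), used by
#'   `gate = "distance"`.
#' @param r_gate H-to-acceptor distance gate (A), used by
#'   `gate = "hydrogen"`.
#' @param acceptor_elements Elements allowed as acceptors (default O
#'   only, matching O-H...O maps).
#' @param donor_chains Restrict donors to these chains (`NULL` = all);
#'   used by the symmetry-aware crystal analysis so that acceptor
#'   environments can be expanded without multiplying donors.
#' @return A tibble of class `wat_geometry_map`: `r_center`,
#'   `theta_center`, `count`, with the edges, the pair class, the total
#'   scored count and the spill count as attributes.
#' @export
geometry_map <- function(traj, pair_class = c("water_water", "water_protein"),
                         r_edges = default_r_edges(),
                         theta_edges = default_theta_edges(),
                         gate = c("distance", "hydrogen"),
                         d_gate = 3.5, r_gate = 4.0,
                         acceptor_elements = "O", donor_chains = NULL) {
  pair_class <- match.arg(pair_class)
  gate <- match.arg(gate)
  traj <- as_trajectory(traj)
  counts <- matrix(0, length(r_edges) - 1L, length(theta_edges) - 1L)
  spill <- 0
  n_scored <- 0
  for (i in seq_len(n_frames(traj))) {
    fr <- frame_structure(traj, i)
    sc <- if (gate == "distance") {
      score_hb_pairs(fr, mode = "score_d", d_max = d_gate)
    } else {
      score_hb_pairs(fr, mode = "score_r", d_max = NA, r_gate = r_gate)
    }
    sc <- sc[sc$acceptor_element %in% acceptor_elements, , drop = FALSE]
    if (!is.null(donor_chains)) {
      sc <- sc[sc$donor_chain %in% donor_chains, , drop = FALSE]
    }
    sc <- filter_pair_class(sc, pair_class)
    if (nrow(sc) == 0) next
    n_scored <- n_scored + nrow(sc)
    # snap tolerance as in the profiles: edge-exact geometries go up
    ri <- findInterval(sc$r + 1e-9, r_edges, rightmost.closed = FALSE)
    ti <- findInterval(sc$theta + 1e-9, theta_edges, rightmost.closed = FALSE)
    ok <- ri >= 1 & ri < length(r_edges) & ti >= 1 & ti < length(theta_edges)
    spill <- spill + sum(!ok)
    for (j in which(ok)) counts[ri[j], ti[j]] <- counts[ri[j], ti[j]] + 1
  }
  rc <- (r_edges[-length(r_edges)] + r_edges[-1]) / 2
  tc <- (theta_edges[-length(theta_edges)] + theta_edges[-1]) / 2
  out <- tibble::tibble(
    r_center = rep(rc, times = length(tc)),
    theta_center = rep(tc, each = length(rc)),
    count = as.vector(counts))
  structure(out,
            r_edges = r_edges, theta_edges = theta_edges,
            pair_class = pair_class, n_scored = n_scored, spill = spill,
            class = c("wat_geometry_map", class(out)))
}

#' @export
dplyr_reconstruct.wat_geometry_map <- function(data, template) {
  out <- NextMethod()
  for (a in c("r_edges", "theta_edges", "pair_class", "n_scored", "spill")) {
    attr(out, a) <- attr(template, a)
  }
  class(out) <- class(template)
  out
}

#' Location of the maximal bin of a geometry map
#'
#' Ties are broken toward smaller r, then smaller theta.
#'
#' @param m A `wat_geometry_map`.
#' @return One-row tibble: `r` and `theta` bin centers of the maximal bin
#'   and its `count`.
#' @export
map_peak <- function(m) {
  if (nrow(m) == 0 || all(m$count == 0)) {
    stop("geometry map is empty; no peak to locate", call. = FALSE)
  }
  ord <- order(-m$count, m$r_center, m$theta_center)
  top <- m[ord[1], ]
  tibble::tibble(r = top$r_center, theta = top$theta_center,
                 count = top$count)
}

#' Hydration-level trends of the profile peaks
#'
#' Reads each class profile at the bins containing the hydrogen-bond
#' distance `d_hb` and the van der Waals contact distance `d_vdw` and
#' tabulates the values against hydration level.
#'
#' @param profiles A list of [surface_distance_profile()] results (each
#'   carrying a distinct `h`), or one long tibble binding them.
#' @param d_hb,d_vdw Probe distances (A); `d_hb < d_vdw` required.
#' @return Tibble ordered by `h`: `h`, `class`, `distance` (`"hb"` or
#'   `"vdw"`), `probe_a`, `value`.
#' @export
peak_trends <- function(profiles, d_hb = 1.8, d_vdw = 2.5) {
  stopifnot(d_hb < d_vdw)
  if (is.data.frame(profiles)) profiles <- list(profiles)
  h_per_profile <- unlist(lapply(profiles, function(p) unique(p$h)))
  if (anyNA(h_per_profile)) {
    stop("every profile needs a hydration level h", call. = FALSE)
  }
  if (anyDuplicated(h_per_profile)) {
    stop("duplicated hydration levels in profiles", call. = FALSE)
  }
  long <- dplyr::bind_rows(lapply(profiles, tibble::as_tibble))
  probe <- tibble::tibble(distance = c("hb", "vdw"), probe_a = c(d_hb, d_vdw))
  out <- tidyr::crossing(dplyr::distinct(long, .data$h, .data$class), probe) |>
    dplyr::rowwise() |>
    dplyr::mutate(value = {
      sel <- long$h == .data$h & long$class == .data$class &
        long$bin_lo <= .data$probe_a & long$bin_hi > .data$probe_a
      if (!any(sel)) NA_real_ else long$count[sel][1]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$h, .data$class, .data$distance)
  out
}

#' Residue-residue contact map between two chains
#'
#' A residue pair is in contact when the minimum heavy-atom minimum-image
#' distance between the two residues is below `cutoff`.
#'
#' @param s A `wat_structure`.
#' @param chain_a,chain_b Distinct chain identifiers.
#' @param cutoff Heavy-atom distance cutoff (A).
#' @return A tibble of class `wat_contact_map`: `resid_a`, `resid_b`,
#'   `dmin`, `contact` (logical), with the chains and cutoff as
#'   attributes. Swapping the chains transposes the map.
#' @export
contact_map <- function(s, chain_a, chain_b, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  if (identical(chain_a, chain_b)) {
    stop("chain_a and chain_b must differ", call. = FALSE)
  }
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  prot <- s$atom_class %in% c("main_chain", "side_chain_hydrophilic",
                              "side_chain_hydrophobic")
  heavy <- prot & toupper(s$element) != "H"
  a <- s[heavy & s$chain == chain_a, ]
  b <- s[heavy & s$chain == chain_b, ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("chain not found or contains no protein heavy atoms", call. = FALSE)
  }
  box <- structure_box(s)
  d <- cross_dist(coords(a), coords(b), box)
  out <- tibble::tibble(
    resid_a = rep(a$resid, ncol(d)),
    resid_b = rep(b$resid, each = nrow(d)),
    d = as.vector(d)) |>
    dplyr::group_by(.data$resid_a, .data$resid_b) |>
    dplyr::summarise(dmin = min(.data$d), .groups = "drop") |>
    dplyr::mutate(contact = .data$dmin < cutoff)
  structure(out, chain_a = chain_a, chain_b = chain_b, cutoff = cutoff,
            class = c("wat_contact_map", class(out)))
}
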