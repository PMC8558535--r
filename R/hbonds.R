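#' Geometric hydrogen-bond criterion
#'
#' A donor--acceptor pair is hydrogen-bonded when the donor-heavy-atom to
#' acceptor distance is strictly below `d_oo_max` and the deviation from
#' linearity theta = 180 - angle(O-H...O) is at most `theta_max` for at
#' least one donor hydrogen (i.e. the O-H...O angle lies in
#' [180 - theta_max, 180], inclusive at the lower edge).
#'
#' @param d_oo_max Donor-heavy to acceptor heavy-atom distance cutoff (A).
#' @param theta_max Maximum deviation from linearity, degrees.
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(d_oo_max = 3.5, theta_max = 60) {
  stopifnot(d_oo_max > 0, theta_max > 0, theta_max <= 90)
  structure(list(d_oo_max = d_oo_max, theta_max = theta_max),
            class = "hbond_criterion")
}

#' Hydrogen-bond geometry of one donor-H-acceptor triple
#'
#' @param donor_o,h,acceptor_o Length-3 position vectors (A).
#' @param box Periodic box edges, or `NULL`.
#' @return One-row tibble with `r`, the H-to-acceptor distance, and
#'   `theta`, 180 degrees minus the angle at the hydrogen between the
#'   donor and the acceptor (0 for a perfectly linear bond).
#' @export
#' @examples
#' hb_geometry(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0)) # r = 1.84, theta = 0
hb_geometry <- function(donor_o, h, acceptor_o, box = NULL) {
  v1 <- min_image_disp(rbind(donor_o - h), box)
  v2 <- min_image_disp(rbind(acceptor_o - h), box)
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9 || sum((v1 - v2)^2) < 1e-18) {
    stop("degenerate geometry: coincident points", call. = FALSE)
  }
  cosang <- max(-1, min(1, sum(v1 * v2) / (n1 * n2)))
  tibble::tibble(r = n2, theta = 180 - acos(cosang) * 180 / pi)
}

# assign each hydrogen to its covalently bonded heavy atom: nearest heavy
# atom of the same residue within `cov_max` (PDB inputs carry no CONECT
# records for waters)
attach_hydrogens <- function(s, cov_max = 1.2) {
  box <- structure_box(s)
  is_h <- toupper(s$element) == "H"
  h_idx <- which(is_h)
  if (length(h_idx) == 0) return(integer(0))
  heavy_idx <- which(!is_h)
  res_key <- paste(s$chain, s$resid)
  parent <- rep(NA_integer_, length(h_idx))
  xyz <- coords(s)
  split_heavy <- split(heavy_idx, res_key[heavy_idx])
  for (j in seq_along(h_idx)) {
    i <- h_idx[j]
    cand <- split_heavy[[res_key[i]]]
    if (is.null(cand)) next
    d <- cross_dist(xyz[i, , drop = FALSE], xyz[cand, , drop = FALSE], box)
    k <- which.min(d)
    if (d[k] <= cov_max) parent[j] <- cand[k]
  }
  stats::setNames(parent, h_idx)
}

# donor-H / acceptor scoring engine shared by bond detection and the
# geometry maps. mode "bond": gate on donor-heavy...acceptor < d_max and
# theta <= theta_max. mode "score_d": same distance gate but no angle
# gate (so the non-bonded band at large theta stays visible). mode
# "score_r": gate on H...acceptor <= r_gate, any angle.
score_hb_pairs <- function(s, mode, d_max, theta_max = NULL, r_gate = NULL) {
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  if (!any(toupper(s$element) == "H")) {
    stop("structure contains no hydrogens; cannot evaluate O-H...O geometry",
         call. = FALSE)
  }
  box <- structure_box(s)
  xyz <- coords(s)
  parent <- attach_hydrogens(s)
  h_all <- as.integer(names(parent))
  keep <- !is.na(parent)
  h_all <- h_all[keep]; parent <- unname(parent[keep])
  prot_classes <- c("main_chain", "side_chain_hydrophilic",
                    "side_chain_hydrophobic")
  el <- toupper(s$element)
  cls <- s$atom_class
  # donors: O or N of water/protein with at least one attached hydrogen
  don_ok <- (el[parent] %in% c("O", "N")) &
    (cls[parent] %in% c("water", prot_classes))
  h_all <- h_all[don_ok]; parent <- parent[don_ok]
  # acceptors: water O, protein O, protein N without attached hydrogen
  has_h <- tabulate(parent, nbins = nrow(s)) > 0
  acc_idx <- which((cls == "water" & el == "O") |
                   (cls %in% prot_classes & el == "O") |
                   (cls %in% prot_classes & el == "N" & !has_h))
  if (length(acc_idx) == 0 || length(h_all) == 0) return(empty_bond_table())
  don_u <- unique(parent)
  # candidate pairs gated on a heavy-atom distance wide enough for either mode
  gate <- if (mode == "score_r") r_gate + 1.2 else d_max
  dd <- cross_dist(xyz[don_u, , drop = FALSE],
                   xyz[acc_idx, , drop = FALSE], box)
  hit <- which(dd < gate, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty_bond_table())
  cand <- tibble::tibble(donor = don_u[hit[, 1]],
                         acceptor = acc_idx[hit[, 2]],
                         d_da = dd[hit])
  res_key <- paste(s$chain, s$resid)
  cand <- cand[cand$donor != cand$acceptor &
                 res_key[cand$donor] != res_key[cand$acceptor], , drop = FALSE]
  if (nrow(cand) == 0) return(empty_bond_table())
  # expand over the donor's hydrogens
  h_by_donor <- split(h_all, parent)
  hs <- h_by_donor[as.character(cand$donor)]
  nh <- lengths(hs)
  pairs <- tibble::tibble(
    donor = rep(cand$donor, nh),
    hydrogen = unlist(hs, use.names = FALSE),
    acceptor = rep(cand$acceptor, nh),
    d_da = rep(cand$d_da, nh))
  v1 <- min_image_disp(xyz[pairs$donor, , drop = FALSE] -
                         xyz[pairs$hydrogen, , drop = FALSE], box)
  v2 <- min_image_disp(xyz[pairs$acceptor, , drop = FALSE] -
                         xyz[pairs$hydrogen, , drop = FALSE], box)
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  cosang <- pmax(-1, pmin(1, rowSums(v1 * v2) / (n1 * n2)))
  pairs$r <- n2
  pairs$theta <- 180 - acos(cosang) * 180 / pi
  ok <- switch(mode,
    bond = pairs$d_da < d_max & pairs$theta <= theta_max,
    score_d = pairs$d_da < d_max,
    score_r = pairs$r <= r_gate)
  pairs <- pairs[ok, , drop = FALSE]
  mol <- molecule_ids(s)
  tibble::tibble(
    donor_serial = s$serial[pairs$donor],
    hydrogen_serial = s$serial[pairs$hydrogen],
    acceptor_serial = s$serial[pairs$acceptor],
    d_da = pairs$d_da, r = pairs$r, theta = pairs$theta,
    donor_class = cls[pairs$donor],
    acceptor_class = cls[pairs$acceptor],
    acceptor_element = el[pairs$acceptor],
    donor_mol = mol[pairs$donor],
    acceptor_mol = mol[pairs$acceptor],
    donor_chain = s$chain[pairs$donor])
}

empty_bond_table <- function() {
  tibble::tibble(donor_serial = integer(), hydrogen_serial = integer(),
                 acceptor_serial = integer(), d_da = numeric(), r = numeric(),
                 theta = numeric(), donor_class = character(),
                 acceptor_class = character(), acceptor_element = character(),
                 donor_mol = character(), acceptor_mol = character(),
                 donor_chain = character())
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion: donor-heavy to acceptor distance
#' strictly below `crit$d_oo_max` (the inter-oxygen distance for
#' water--water pairs) and theta at most `crit$theta_max` for the donor
#' hydrogen. Donors are water and protein O-H and N-H groups; acceptors
#' are water oxygens, protein oxygens, and protein nitrogens bearing no
#' hydrogen. Each (donor hydrogen, acceptor) pair is reported at most
#' once.
#'
#' @param s A `wat_structure` with explicit hydrogens (classified with
#'   [classify_atoms()] if an `atom_class` column is absent).
#' @param crit An [hbond_criterion()].
#' @param pairs Restrict the report: `"all"`, `"water_water"`, or
#'   `"water_protein"`.
#' @param acceptor_elements Acceptor elements kept in the report; default
#'   includes nitrogen acceptors, set to `"O"` for O-only analyses.
#' @return Tibble of bonds: serials of donor heavy atom, hydrogen and
#'   acceptor; `d_da` (donor-acceptor heavy distance), `r`
#'   (H-to-acceptor), `theta`; classes and molecule ids of both partners.
#' @export
find_hbonds <- function(s, crit = hbond_criterion(),
                        pairs = c("all", "water_water", "water_protein"),
                        acceptor_elements = c("O", "N")) {
  pairs <- match.arg(pairs)
  bonds <- score_hb_pairs(s, mode = "bond",
                          d_max = crit$d_oo_max, theta_max = crit$theta_max)
  bonds <- bonds[bonds$acceptor_element %in% acceptor_elements, , drop = FALSE]
  filter_pair_class(bonds, pairs)
}

filter_pair_class <- function(bonds, pairs) {
  if (pairs == "all") return(bonds)
  prot <- c("main_chain", "side_chain_hydrophilic", "side_chain_hydrophobic")
  dw <- bonds$donor_class == "water"
  aw <- bonds$acceptor_class == "water"
  keep <- switch(pairs,
    water_water = dw & aw,
    water_protein = (dw & bonds$acceptor_class %in% prot) |
      (aw & bonds$donor_class %in% prot))
  bonds[keep, , drop = FALSE]
}

#' Mean hydrogen bonds per water, decomposed by partner class
#'
#' For every frame, counts each water molecule's bonds (whether the water
#' is donor or acceptor) and splits them by partner: another water, or
#' protein (further split into main chain and side chain). Waters are
#' averaged within each frame, then frames are averaged.
#'
#' @param traj A `wat_trajectory` (or a single structure).
#' @param crit An [hbond_criterion()].
#' @param h Optional hydration level to record alongside the summary.
#' @return One-row tibble: `n_frames`, `n_waters`, `total`, `water_water`,
#'   `water_protein`, `water_main_chain`, `water_side_chain`. The
#'   water--water and water--protein means sum to the total, and the main-
#'   and side-chain means sum to the water--protein mean.
#' @export
per_water_counts <- function(traj, crit = hbond_criterion(), h = NA_real_) {
  traj <- as_trajectory(traj)
  top <- traj$topology
  if (!"atom_class" %in% names(top)) {
    top <- suppressWarnings(classify_atoms(top))
  }
  waters <- unique(molecule_ids(top)[top$atom_class == "water"])
  if (length(waters) == 0) {
    stop("no water molecules in the system", call. = FALSE)
  }
  per_frame <- purrr::map(seq_len(n_frames(traj)), function(i) {
    fr <- frame_structure(traj, i)
    if (!"atom_class" %in% names(fr)) {
      fr <- suppressWarnings(classify_atoms(fr))
    }
    bonds <- find_hbonds(fr, crit)
    count_water_bonds(bonds, waters)
  })
  means <- purrr::map(per_frame, ~colMeans(.x))
  avg <- Reduce(`+`, means) / length(means)
  tibble::tibble(
    h = h, n_frames = n_frames(traj), n_waters = length(waters),
    total = avg[["total"]],
    water_water = avg[["water_water"]],
    water_protein = avg[["water_protein"]],
    water_main_chain = avg[["water_main_chain"]],
    water_side_chain = avg[["water_side_chain"]])
}

# per-water bond counts for one frame's bond table
count_water_bonds <- function(bonds, waters) {
  prot <- c("main_chain", "side_chain_hydrophilic", "side_chain_hydrophobic")
  zero <- stats::setNames(numeric(length(waters)), waters)
  acc <- list(total = zero, water_water = zero, water_protein = zero,
              water_main_chain = zero, water_side_chain = zero)
  tally <- function(vec, ids) {
    t <- table(factor(ids, levels = waters))
    vec + as.numeric(t)
  }
  if (nrow(bonds) > 0) {
    for (side in c("donor", "acceptor")) {
      own <- bonds[[paste0(side, "_class")]] == "water"
      partner_cls <- bonds[[paste0(setdiff(c("donor", "acceptor"), side),
                                   "_class")]]
      own_mol <- bonds[[paste0(side, "_mol")]][own]
      pc <- partner_cls[own]
      acc$total <- tally(acc$total, own_mol)
      acc$water_water <- tally(acc$water_water, own_mol[pc == "water"])
      acc$water_protein <- tally(acc$water_protein, own_mol[pc %in% prot])
      acc$water_main_chain <- tally(acc$water_main_chain,
                                    own_mol[pc == "main_chain"])
      acc$water_side_chain <- tally(
        acc$water_side_chain,
        own_mol[pc %in% c("side_chain_hydrophilic", "side_chain_hydrophobic")])
    }
  }
  do.call(cbind, acc)
}

#' Water hydrogen-bond network graph
#'
#' @param bonds A bond tibble from [find_hbonds()]; bonds with non-water
#'   partners are ignored, parallel bonds between the same two waters
#'   collapse to one edge.
#' @return An undirected simple `igraph` graph whose vertices are water
#'   molecule identifiers.
#' @export
water_network <- function(bonds) {
  ww <- bonds[bonds$donor_class == "water" & bonds$acceptor_class == "water", ]
  verts <- unique(c(ww$donor_mol, ww$acceptor_mol))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ww$donor_mol, to = ww$acceptor_mol),
    directed = FALSE,
    vertices = if (length(verts)) data.frame(name = verts) else NULL)
  igraph::simplify(g)
}

#' Minimal rings of a hydrogen-bond network
#'
#' Finds the smallest rings (chordless minimal cycles) of size at most
#' `max_size`: for every edge, the shortest cycles through that edge are
#' enumerated via shortest paths in the graph with the edge removed, and
#' duplicates under rotation and reflection are merged.
#'
#' @param g An undirected `igraph` graph (e.g. from [water_network()]).
#' @param max_size Largest ring size to report (>= 3).
#' @return Tibble with `ring_id`, `size`, and `members`, a list-column of
#'   vertex-name vectors in cycle order.
#' @export
find_rings <- function(g, max_size = 6) {
  stopifnot(max_size >= 3)
  rings <- list()
  el <- igraph::as_edgelist(g, names = FALSE)
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g2, from = u, to = v)$vpaths)
    for (p in sp) {
      cyc <- as.integer(p)
      if (length(cyc) >= 3 && length(cyc) <= max_size) {
        rings[[length(rings) + 1L]] <- canonical_cycle(cyc)
      }
    }
  }
  rings <- unique(rings)
  nm <- igraph::V(g)$name
  tibble::tibble(
    ring_id = seq_along(rings),
    size = vapply(rings, length, integer(1)),
    members = lapply(rings, function(r) {
      if (is.null(nm)) as.character(r) else nm[r]
    }))
}

# rotate/reflect a cycle to a canonical form for deduplication
canonical_cycle <- function(cyc) {
  n <- length(cyc)
  k <- which.min(cyc)
  fwd <- cyc[((seq_len(n) + k - 2L) %% n) + 1L]
  rev_ <- rev(cyc)
  k2 <- which.min(rev_)
  bwd <- rev_[((seq_len(n) + k2 - 2L) %% n) + 1L]
  if (paste(fwd, collapse = ",") <= paste(bwd, collapse = ",")) fwd else bwd
}

#' Keep rings close to atoms of one class
#'
#' A ring is kept when at least one member water oxygen lies within
#' `cutoff` of any atom of `target_class` (minimum image). The default 4 A
#' cutoff is the hydration-shell membership distance.
#'
#' @param rings Ring tibble from [find_rings()].
#' @param s The classified frame the rings were found in.
#' @param target_class One of the [classify_atoms()] labels.
#' @param cutoff Distance cutoff (A).
#' @return The subset of `rings` near the class.
#' @export
rings_near_class <- function(rings, s, target_class, cutoff = 4) {
  stopifnot(cutoff > 0)
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  valid <- c("water", "ion", "main_chain", "side_chain_hydrophilic",
             "side_chain_hydrophobic")
  if (!target_class %in% valid) {
    stop("unknown atom class '", target_class, "'", call. = FALSE)
  }
  if (nrow(rings) == 0) return(rings)
  target <- coords(s)[s$atom_class == target_class, , drop = FALSE]
  if (nrow(target) == 0) return(rings[0, ])
  box <- structure_box(s)
  mol <- molecule_ids(s)
  is_wo <- s$atom_class == "water" & toupper(s$element) == "O"
  keep <- vapply(rings$members, function(mem) {
    o <- coords(s)[is_wo & mol %in% mem, , drop = FALSE]
    nrow(o) > 0 && min(cross_dist(o, target, box)) < cutoff
  }, logical(1))
  rings[keep, , drop = FALSE]
}
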