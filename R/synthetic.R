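#' Rigid three-site water model parameters
#'
#' Defaults are the standard rigid three-site (TIP3P-type) constants:
#' O-H 0.9572 A, H-O-H 104.52 degrees, charges -0.834 e on O and
#' +0.417 e on H, Lennard-Jones on oxygen only (sigma 3.1507 A, epsilon
#' 0.1521 kcal/mol), and a 10 A spherical cutoff.
#'
#' @param oh_length O-H bond length (A).
#' @param hoh_angle H-O-H angle (degrees).
#' @param q_o,q_h Partial charges (e); must sum to zero per molecule.
#' @param sigma,epsilon Oxygen Lennard-Jones parameters (A, kcal/mol).
#' @param cutoff Spherical O-O cutoff (A).
#' @return A `water_model` parameter list.
#' @export
water_model <- function(oh_length = 0.9572, hoh_angle = 104.52,
                        q_o = -0.834, q_h = 0.417,
                        sigma = 3.1507, epsilon = 0.1521, cutoff = 10) {
  if (abs(q_o + 2 * q_h) > 1e-9) {
    stop("water charges must sum to zero", call. = FALSE)
  }
  structure(list(oh_length = oh_length, hoh_angle = hoh_angle,
                 q_o = q_o, q_h = q_h, sigma = sigma, epsilon = epsilon,
                 cutoff = cutoff),
            class = "water_model")
}

#' Monte Carlo sampler settings
#'
#' @param n_waters Number of water molecules (default 440, the bulk
#'   reference system size).
#' @param temperature Temperature in K.
#' @param density Mass density in g/cm3; sets the cubic box edge.
#' @param dt Maximum translation per move (A).
#' @param rot Maximum rotation per move (degrees).
#' @param n_sweeps Production sweeps (one sweep = one attempted move per
#'   molecule).
#' @param equilibration_sweeps Sweeps discarded before sampling.
#' @param sample_interval Sweeps between recorded frames.
#' @param seed Integer RNG seed.
#' @return An `mc_settings` list.
#' @export
mc_settings <- function(n_waters = 440, temperature = 300, density = 1.0,
                        dt = 0.25, rot = 25,
                        n_sweeps = 2000, equilibration_sweeps = 2000,
                        sample_interval = 20, seed = 1L) {
  stopifnot(n_waters > 0, temperature > 0, density > 0,
            n_sweeps >= 0, equilibration_sweeps >= 0, sample_interval >= 1)
  structure(list(n_waters = as.integer(n_waters), temperature = temperature,
                 density = density, dt = dt, rot = rot,
                 n_sweeps = as.integer(n_sweeps),
                 equilibration_sweeps = as.integer(equilibration_sweeps),
                 sample_interval = as.integer(sample_interval),
                 seed = as.integer(seed)),
            class = "mc_settings")
}

# cubic box edge (A) for n waters at the given density (g/cm3)
water_box_edge <- function(n_waters, density, water_mass = 18.015) {
  avogadro <- 6.02214076e23
  (n_waters * water_mass / (avogadro * density))^(1 / 3) * 1e8
}

water_topology <- function(n, box = NULL, chain = "W") {
  new_structure(tibble::tibble(
    serial = seq_len(3L * n),
    name = rep(c("O", "H1", "H2"), n),
    element = rep(c("O", "H", "H"), n),
    resname = "HOH",
    resid = rep(seq_len(n), each = 3L),
    chain = chain,
    x = 0, y = 0, z = 0, occupancy = 1, altloc = ""), box = box)
}

#' Ideal ice-rule water lattice
#'
#' Places oxygens on a cubic-ice-like diamond lattice (nearest O-O
#' distance `o_o`, default 2.76 A) in a periodic box of `n_cells` cells
#' per axis, then assigns protons by orienting an Eulerian circuit of the
#' 4-regular neighbour graph: every oxygen gets exactly two covalent
#' hydrogens and every O-O link carries exactly one hydrogen (the ice
#' rules). Hydrogens lie on the O-O axes, so every bond is perfectly
#' linear. Optional Gaussian jitter displaces each molecule rigidly
#' (hydrogens move with their oxygen, staying covalently attached), the
#' way static positional disorder perturbs a lattice.
#'
#' @param n_cells Cells per axis (>= 2); 8 waters per cell.
#' @param jitter_sigma Gaussian positional noise, A.
#' @param seed Integer seed (proton assignment and jitter).
#' @param o_o Nearest-neighbour O-O distance (A).
#' @param oh_length Covalent O-H length (A).
#' @return A `wat_structure` of `8 n_cells^3` waters with a periodic box.
#' @export
make_ice_lattice <- function(n_cells = 3, jitter_sigma = 0, seed = 1L,
                             o_o = 2.76, oh_length = 0.9572) {
  stopifnot(n_cells >= 2)
  a <- o_o * 4 / sqrt(3)
  base <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(base, sweep(base, 2, c(.25, .25, .25), "+"))
  cells <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1),
                                 0:(n_cells - 1)))
  frac <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sweep(basis, 2, cells[i, ], "+")
  })) / n_cells
  box <- rep(a * n_cells, 3)
  o_xyz <- sweep(frac, 2, box, "*")
  n <- nrow(o_xyz)
  # 4-regular neighbour graph at the nearest-neighbour distance
  d <- cross_dist(o_xyz, o_xyz, box)
  adj <- which(d > 1e-6 & d < o_o + 0.1, arr.ind = TRUE)
  adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  perm <- sample.int(n)
  g <- igraph::make_undirected_graph(
    as.vector(t(cbind(perm[adj[, 1]], perm[adj[, 2]]))), n = n)
  circuit <- as.integer(igraph::eulerian_cycle(g)$vpath)
  inv <- order(perm)  # back to lattice indexing
  circuit <- inv[circuit]
  # orient edges along the circuit: out-degree 2 per oxygen
  donors <- circuit[-length(circuit)]
  targets <- circuit[-1]
  h_list <- vector("list", n)
  for (k in seq_along(donors)) {
    i <- donors[k]; j <- targets[k]
    u <- min_image_disp(rbind(o_xyz[j, ] - o_xyz[i, ]), box)
    u <- u / sqrt(sum(u^2))
    h_list[[i]] <- rbind(h_list[[i]], o_xyz[i, ] + oh_length * u)
  }
  stopifnot(all(vapply(h_list, nrow, integer(1)) == 2L))
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(o_xyz[i, ], h_list[[i]])
  }))
  if (jitter_sigma > 0) {
    shift <- matrix(stats::rnorm(3 * n, sd = jitter_sigma), n, 3)
    xyz <- xyz + shift[rep(seq_len(n), each = 3), ]
  }
  top <- water_topology(n, box = box)
  top$x <- xyz[, 1]; top$y <- xyz[, 2]; top$z <- xyz[, 3]
  top
}

#' Planar water-ring fixture
#'
#' Places `n_members` waters at the vertices of a regular polygon with
#' side `o_o` in the z = 0 plane; each water donates one hydrogen along
#' the edge to the next vertex, so the hydrogen-bond cycle closes into a
#' single n-membered ring. The second hydrogen points out of the plane.
#'
#' @param n_members Ring size (>= 3).
#' @param o_o Edge O-O distance (A); the default 2.8 A is a typical
#'   water-water hydrogen-bond length.
#' @param oh_length,hoh_angle Rigid water geometry.
#' @return A `wat_structure` (no periodic box).
#' @export
make_ring_fixture <- function(n_members = 5, o_o = 2.8,
                              oh_length = 0.9572, hoh_angle = 104.52) {
  if (n_members < 3) {
    stop("a ring needs at least 3 members", call. = FALSE)
  }
  rad <- o_o / (2 * sin(pi / n_members))
  ang <- 2 * pi * (seq_len(n_members) - 1) / n_members
  o_xyz <- cbind(rad * cos(ang), rad * sin(ang), 0)
  nxt <- c(seq_len(n_members)[-1], 1L)
  xyz <- do.call(rbind, lapply(seq_len(n_members), function(i) {
    e <- o_xyz[nxt[i], ] - o_xyz[i, ]
    e <- e / sqrt(sum(e^2))
    h1 <- o_xyz[i, ] + oh_length * e
    # second hydrogen tilted out of the ring plane, preserving the
    # H-O-H angle
    d2 <- cos(hoh_angle * pi / 180) * e +
      sin(hoh_angle * pi / 180) * c(0, 0, 1)
    h2 <- o_xyz[i, ] + oh_length * d2
    rbind(o_xyz[i, ], h1, h2)
  }))
  top <- water_topology(n_members)
  top$x <- xyz[, 1]; top$y <- xyz[, 2]; top$z <- xyz[, 3]
  top
}

#' Toy protein-surface fixture with waters at prescribed distances
#'
#' Builds a sparse slab of protein-like sites on the z = 0 plane:
#' hydrogen-bond sites (a backbone amide N-H pointing up, with a water
#' oxygen exactly 1.8 A above the amide hydrogen, in a bond-competent
#' collinear arrangement) and van der Waals sites (a hydrophobic LEU CD1
#' carbon with a water oxygen exactly 2.5 A above it). Sites are spaced
#' widely enough that each water's nearest protein atom is its own
#' site's.
#'
#' @param n_waters_hb Waters at the hydrogen-bond distance (1.8 A).
#' @param n_waters_vdw Waters at the van der Waals distance (2.5 A).
#' @param seed Seed for the in-plane water orientations.
#' @param d_hb,d_vdw The two prescribed surface distances (A).
#' @param spacing Site grid spacing (A); must exceed twice the largest
#'   profile distance of interest.
#' @param max_sites Capacity cap on the slab.
#' @return A `wat_structure` (no periodic box).
#' @export
make_toy_surface <- function(n_waters_hb, n_waters_vdw, seed = 1L,
                             d_hb = 1.8, d_vdw = 2.5, spacing = 16,
                             max_sites = 1024) {
  stopifnot(n_waters_hb >= 0, n_waters_vdw >= 0)
  n_sites <- n_waters_hb + n_waters_vdw
  if (n_sites > max_sites) {
    stop("slab capacity exceeded: ", n_sites, " sites requested, cap ",
         max_sites, call. = FALSE)
  }
  ncol_grid <- max(1L, ceiling(sqrt(max(n_sites, 1L))))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  rows <- list()
  serial <- 0L
  add <- function(name, element, resname, resid, chain, p) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      serial = serial, name = name, element = element, resname = resname,
      resid = resid, chain = chain, x = p[1], y = p[2], z = p[3],
      occupancy = 1, altloc = "")
  }
  oh <- 0.9572
  hoh <- 104.52 * pi / 180
  # anchor residue so the slab exists even with zero waters requested
  add("CA", "C", "GLY", n_sites + 1L, "P", c(-spacing, -spacing, 0))
  wat_res <- n_sites + 1L  # water resids continue after sites
  for (i in seq_len(n_sites)) {
    gx <- ((i - 1) %% ncol_grid) * spacing
    gy <- ((i - 1) %/% ncol_grid) * spacing
    if (i <= n_waters_hb) {
      # amide N at z=0, its H at z=1.0; water O collinear above at d_hb
      add("N", "N", "SER", i, "P", c(gx, gy, 0))
      add("H", "H", "SER", i, "P", c(gx, gy, 1.0))
      o <- c(gx, gy, 1.0 + d_hb)
      wat_res <- wat_res + 1L
      add("O", "O", "HOH", wat_res, "W", o)
      # water hydrogens point upward, away from the surface
      phi <- stats::runif(1, 0, 2 * pi)
      d1 <- c(cos(phi) * sin(hoh / 2), sin(phi) * sin(hoh / 2), cos(hoh / 2))
      d2 <- c(-cos(phi) * sin(hoh / 2), -sin(phi) * sin(hoh / 2),
              cos(hoh / 2))
      add("H1", "H", "HOH", wat_res, "W", o + oh * d1)
      add("H2", "H", "HOH", wat_res, "W", o + oh * d2)
    } else {
      add("CD1", "C", "LEU", i, "P", c(gx, gy, 0))
      o <- c(gx, gy, d_vdw)
      wat_res <- wat_res + 1L
      add("O", "O", "HOH", wat_res, "W", o)
      phi <- stats::runif(1, 0, 2 * pi)
      d1 <- c(cos(phi) * sin(hoh / 2), sin(phi) * sin(hoh / 2), cos(hoh / 2))
      d2 <- c(-cos(phi) * sin(hoh / 2), -sin(phi) * sin(hoh / 2),
              cos(hoh / 2))
      add("H1", "H", "HOH", wat_res, "W", o + oh * d1)
      add("H2", "H", "HOH", wat_res, "W", o + oh * d2)
    }
  }
  new_structure(dplyr::bind_rows(rows))
}

#' Equilibrated bulk-water sample by rigid-water Monte Carlo
#'
#' Runs Metropolis Monte Carlo of rigid three-site waters in a cubic
#' minimum-image box sized from the density: single-molecule moves
#' (random translation plus random rigid rotation about the oxygen),
#' energy from oxygen Lennard-Jones and all-site Coulomb terms under a
#' spherical O-O cutoff, Boltzmann acceptance at the set temperature.
#' Move sizes are auto-tuned toward ~40% acceptance during the first
#' half of equilibration and then held fixed. Frames are recorded every
#' `sample_interval` sweeps after equilibration. If the equilibration
#' energy has not plateaued (running means of the last two quarters
#' differing by more than 1%), equilibration is extended up to
#' `max_extensions` times.
#'
#' @param settings An [mc_settings()] list.
#' @param params A [water_model()] parameter list.
#' @param max_extensions Extra equilibration blocks allowed by the
#'   plateau check.
#' @return A `wat_trajectory` whose attributes carry the per-sweep
#'   `energy` trace (kcal/mol), the `acceptance` rate, and the final
#'   move sizes.
#' @export
mc_bulk_water <- function(settings = mc_settings(), params = water_model(),
                          max_extensions = 3) {
  n <- settings$n_waters
  edge <- water_box_edge(n, settings$density)
  if (params$cutoff > edge / 2) {
    warning("cutoff ", params$cutoff, " A exceeds half the box edge (",
            round(edge / 2, 2), " A); interactions are truncated at the ",
            "minimum image", call. = FALSE)
  }
  kT <- 0.0019872041 * settings$temperature
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(settings$seed)
  xyz <- initial_water_grid(n, edge, params)
  equil <- settings$equilibration_sweeps
  energy <- numeric(0)
  res <- mc_water_run(xyz, n, edge, params$epsilon, params$sigma,
                      params$q_o, params$q_h, min(params$cutoff, edge / 2),
                      kT, equil, 0L, 1L,
                      settings$dt, settings$rot * pi / 180, TRUE)
  energy <- c(energy, res$energy)
  ext <- 0
  while (!mc_plateaued(energy) && ext < max_extensions && equil > 0) {
    xyz <- res$coords
    res <- mc_water_run(xyz, n, edge, params$epsilon, params$sigma,
                        params$q_o, params$q_h, min(params$cutoff, edge / 2),
                        kT, equil, 0L, 1L, res$dt, res$rot, FALSE)
    energy <- c(energy, res$energy)
    ext <- ext + 1
  }
  xyz <- res$coords
  prod <- mc_water_run(xyz, n, edge, params$epsilon, params$sigma,
                       params$q_o, params$q_h, min(params$cutoff, edge / 2),
                       kT, 0L, settings$n_sweeps, settings$sample_interval,
                       res$dt, res$rot, FALSE)
  energy <- c(energy, prod$energy)
  if (prod$acceptance < 0.05 || prod$acceptance > 0.95) {
    warning("Monte Carlo acceptance rate ", round(prod$acceptance, 3),
            " outside (0.05, 0.95); sampling may be inefficient",
            call. = FALSE)
  }
  top <- water_topology(n, box = rep(edge, 3))
  traj <- new_trajectory(top, prod$frames)
  attr(traj, "energy") <- energy
  attr(traj, "acceptance") <- prod$acceptance
  attr(traj, "move_sizes") <- c(dt = prod$dt, rot = prod$rot)
  attr(traj, "equilibrated") <- mc_plateaued(energy[seq_len(
    length(energy) - settings$n_sweeps)])
  traj
}

# running-mean plateau: the last two quarters of the trace differ by <1%
mc_plateaued <- function(energy) {
  n <- length(energy)
  if (n < 40) return(FALSE)
  q3 <- energy[(n - n %/% 2 + 1):(n - n %/% 4)]
  q4 <- energy[(n - n %/% 4 + 1):n]
  m3 <- mean(q3); m4 <- mean(q4)
  denom <- max(abs(m4), 1e-8)
  abs(m4 - m3) / denom < 0.01
}

# simple-cubic oxygen grid with random molecular orientations
initial_water_grid <- function(n, edge, params) {
  per_axis <- ceiling(n^(1 / 3))
  sp <- edge / per_axis
  grid <- as.matrix(expand.grid(seq_len(per_axis), seq_len(per_axis),
                                seq_len(per_axis)))[seq_len(n), , drop = FALSE]
  o <- (grid - 0.5) * sp
  sites <- rigid_water_sites(params$oh_length, params$hoh_angle)
  do.call(rbind, lapply(seq_len(n), function(i) {
    t(random_rotation() %*% t(sites)) + matrix(o[i, ], 3, 3, byrow = TRUE)
  }))
}

#' Oxygen-oxygen radial distribution function
#'
#' @param traj A water trajectory with a periodic box.
#' @param dr Shell width (A).
#' @param r_max Largest distance (defaults to half the box edge).
#' @return Tibble with `r` (shell centers) and `g`.
#' @export
oo_rdf <- function(traj, dr = 0.05, r_max = NULL) {
  traj <- as_trajectory(traj)
  top <- traj$topology
  is_o <- toupper(top$element) == "O"
  box <- traj$boxes[[1]]
  if (is.null(box)) stop("RDF needs a periodic box", call. = FALSE)
  if (is.null(r_max)) r_max <- min(box) / 2
  edges <- seq(0, r_max, by = dr)
  counts <- numeric(length(edges) - 1L)
  n_o <- sum(is_o)
  for (i in seq_len(n_frames(traj))) {
    o <- traj$coords[[i]][is_o, , drop = FALSE]
    d <- cross_dist(o, o, box)
    d <- d[upper.tri(d)]
    d <- d[d < r_max]
    counts <- counts + as.numeric(table(cut(d, edges, right = FALSE)))
  }
  counts <- counts / n_frames(traj)
  vol <- prod(box)
  rho_pairs <- n_o * (n_o - 1) / 2 / vol
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  tibble::tibble(r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = counts / (rho_pairs * shell_vol))
}

#' Write a synthetic crystal-entry fixture set
#'
#' Writes each structure of `entry_spec` as a PDB file named after its
#' entry id, plus a `manifest.csv` with the method and resolution
#' metadata, ready for [read_entry_set()] / [filter_entries()].
#'
#' @param entry_spec Tibble with columns `entry_id`, `method`,
#'   `resolution` and a `structure` list-column.
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble (with a `path` column), invisibly the
#'   same as written to `manifest.csv`.
#' @export
make_fixture_entry_set <- function(entry_spec, out_dir) {
  entry_spec <- tibble::as_tibble(entry_spec)
  if (anyDuplicated(entry_spec$entry_id)) {
    stop("duplicate entry ids in fixture specification", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(entry_spec))
  for (i in seq_len(nrow(entry_spec))) {
    paths[i] <- paste0(entry_spec$entry_id[i], ".pdb")
    write_structure(entry_spec$structure[[i]], file.path(out_dir, paths[i]))
  }
  manifest <- tibble::tibble(entry_id = entry_spec$entry_id,
                             method = entry_spec$method,
                             resolution = entry_spec$resolution,
                             path = paths)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
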