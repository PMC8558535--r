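#' Space-group symmetry operators
#'
#' Returns the symmetry operators of a supported space group as rotation
#' matrices and translation vectors acting on fractional coordinates.
#' Supported groups are `P1` (identity) and `P41` (tetragonal, 4_1 screw
#' axis, four operators).
#'
#' @param name Space-group symbol, `"P1"` or `"P41"` (also accepted with
#'   spaces or subscript-style digits, e.g. `"P 41"`).
#' @return A list with `name` and `operators`, each operator a list with a
#'   3x3 matrix `R` and length-3 vector `t` (fractional).
#' @export
space_group_ops <- function(name) {
  key <- toupper(gsub("[ _]", "", name))
  op <- function(R, t) list(R = matrix(R, 3, 3, byrow = TRUE), t = t)
  lattice <- switch(key, "P1" = "triclinic", "P41" = "tetragonal")
  ops <- switch(key,
    "P1" = list(op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0))),
    "P41" = list(
      op(c(1, 0, 0, 0, 1, 0, 0, 0, 1), c(0, 0, 0)),
      op(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), c(0, 0, 1 / 2)),
      op(c(0, -1, 0, 1, 0, 0, 0, 0, 1), c(0, 0, 1 / 4)),
      op(c(0, 1, 0, -1, 0, 0, 0, 0, 1), c(0, 0, 3 / 4))
    ),
    stop("unknown space group '", name, "'; supported: P1, P41",
         call. = FALSE)
  )
  list(name = key, operators = ops, lattice = lattice)
}

# molecule grouping: each water/ion residue is its own molecule, every
# other (protein) chain is one molecule, so centroid wrapping never splits
# a covalent unit
molecule_ids <- function(s) {
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  small <- s$atom_class %in% c("water", "ion")
  ifelse(small, paste0("r", s$chain, ":", s$resid), paste0("c", s$chain))
}

#' Expand an asymmetric unit by space-group symmetry
#'
#' Applies every operator of the group to the asymmetric unit in
#' fractional coordinates of the given cell, then wraps each molecule into
#' the unit cell by its centroid (so no molecule is split across the cell
#' boundary). Copies get distinct chain identifiers and fresh serials.
#'
#' @param asym A `wat_structure`, the asymmetric unit.
#' @param ops Result of [space_group_ops()] (or a group name).
#' @param cell Length-3 cell edge vector in Angstrom (defaults to the
#'   structure's box).
#' @return A `wat_structure` with `length(operators)` copies and `cell` as
#'   its box.
#' @export
apply_space_group <- function(asym, ops, cell = structure_box(asym)) {
  stopifnot(inherits(asym, "wat_structure"), nrow(asym) > 0)
  if (is.character(ops)) ops <- space_group_ops(ops)
  cell <- validate_box(cell)
  if (identical(ops$lattice, "tetragonal") &&
      abs(cell[1] - cell[2]) > 1e-6) {
    stop("a tetragonal space group needs a cell with a = b; got a = ",
         cell[1], ", b = ", cell[2], call. = FALSE)
  }
  frac <- sweep(coords(asym), 2, cell, "/")
  mol <- molecule_ids(asym)
  chains <- unique(asym$chain)
  n_ops <- length(ops$operators)
  chain_pool <- c(LETTERS, letters, as.character(0:9))
  if (n_ops * length(chains) > length(chain_pool)) {
    stop("too many chains to relabel uniquely", call. = FALSE)
  }
  copies <- vector("list", n_ops)
  for (k in seq_len(n_ops)) {
    o <- ops$operators[[k]]
    f <- t(o$R %*% t(frac)) + matrix(o$t, nrow(frac), 3, byrow = TRUE)
    # wrap per molecule by centroid
    for (m in unique(mol)) {
      idx <- mol == m
      shift <- floor(colMeans(f[idx, , drop = FALSE]))
      f[idx, ] <- sweep(f[idx, , drop = FALSE], 2, shift, "-")
    }
    xyz <- sweep(f, 2, cell, "*")
    cp <- asym
    cp$x <- xyz[, 1]; cp$y <- xyz[, 2]; cp$z <- xyz[, 3]
    cp$chain <- chain_pool[(k - 1L) * length(chains) + match(cp$chain, chains)]
    copies[[k]] <- tibble::as_tibble(cp)
  }
  out <- dplyr::bind_rows(copies)
  out$serial <- seq_len(nrow(out))
  new_structure(out, box = cell,
                metadata = c(structure_metadata(asym),
                             list(space_group = ops$name)))
}

#' Number of waters for a target hydration level
#'
#' The hydration level h is grams of water per gram of protein; the water
#' count is `round(h * protein_mass / water_mass)`.
#'
#' @param h Hydration level (g water / g protein), non-negative.
#' @param protein_mass Protein mass in Dalton (see [protein_mass()]).
#' @param water_mass Molar mass of one water, Dalton.
#' @return Integer water count.
#' @export
#' @examples
#' water_count_for_h(0.10, 18015) # 100
water_count_for_h <- function(h, protein_mass, water_mass = 18.015) {
  if (any(h < 0)) stop("hydration level h must be non-negative", call. = FALSE)
  stopifnot(protein_mass > 0)
  as.integer(round(h * protein_mass / water_mass))
}

#' Realized hydration level of a structure
#' @param s A `wat_structure` containing protein and water.
#' @return h in g water / g protein.
#' @export
hydration_level <- function(s) {
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  wat_mass <- sum(atomic_mass(s$element[s$atom_class == "water"]))
  wat_mass / protein_mass(s)
}

# rigid 3-site water geometry: O at origin, H's in the xy plane
rigid_water_sites <- function(oh = 0.9572, hoh = 104.52) {
  a <- hoh * pi / 180
  rbind(c(0, 0, 0),
        c(oh, 0, 0),
        c(oh * cos(a), oh * sin(a), 0))
}

random_rotation <- function() {
  # uniform over SO(3) via random quaternion
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

next_ids <- function(s) {
  list(serial = max(s$serial) + 1L, resid = max(s$resid) + 1L)
}

#' Insert rigid waters at random non-clashing positions
#'
#' Adds `n` three-site rigid waters by rejection sampling: positions
#' uniform in the box, orientations uniform over rotations; a placement is
#' accepted only if its oxygen is at least `clash_cutoff` from every
#' existing heavy (non-hydrogen) atom and every previously placed oxygen
#' under the minimum image. Reproducible for a fixed `seed`.
#'
#' @param s A `wat_structure` with a periodic box.
#' @param n Number of waters to add.
#' @param clash_cutoff Minimum allowed oxygen-to-heavy-atom distance (A).
#' @param seed Integer RNG seed.
#' @param max_attempts Attempt cap per molecule before giving up.
#' @param chain Chain identifier for the new waters.
#' @return `s` with `3 n` atoms appended (residue name HOH).
#' @export
insert_waters <- function(s, n, clash_cutoff = 2.4, seed = 1L,
                          max_attempts = 10000L, chain = "W") {
  stopifnot(inherits(s, "wat_structure"), n >= 0)
  box <- structure_box(s)
  if (is.null(box)) stop("insert_waters needs a periodic box", call. = FALSE)
  if (n == 0) return(s)
  heavy <- coords(s)[toupper(s$element) != "H", , drop = FALSE]
  sites <- rigid_water_sites()
  ids <- next_ids(s)
  placed_o <- matrix(0, 0, 3)
  rows <- vector("list", n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      o <- stats::runif(3) * box
      ref <- rbind(heavy, placed_o)
      if (nrow(ref) > 0 &&
          min(cross_dist(rbind(o), ref, box)) < clash_cutoff) next
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place water ", i, " of ", n, " after ", max_attempts,
           " attempts (", i - 1L, " placed); box too crowded", call. = FALSE)
    }
    xyz <- t(random_rotation() %*% t(sites)) +
      matrix(o, 3, 3, byrow = TRUE)
    rows[[i]] <- tibble::tibble(
      serial = ids$serial + 3L * (i - 1L) + 0:2,
      name = c("O", "H1", "H2"), element = c("O", "H", "H"),
      resname = "HOH", resid = ids$resid + i - 1L, chain = chain,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, altloc = "")
    placed_o <- rbind(placed_o, o)
  }
  rows <- dplyr::bind_rows(rows)
  if ("atom_class" %in% names(s)) rows$atom_class <- "water"
  new_structure(dplyr::bind_rows(tibble::as_tibble(s), rows),
                box = box, metadata = structure_metadata(s))
}

#' Default residue-level formal-charge rules
#'
#' ASP and GLU carry -1, LYS and ARG +1, HIS 0 (neutral tautomer);
#' protonated histidine variants (HIP) carry +1, deprotonated ASH/GLH 0,
#' neutral LYN 0. Chain termini contribute +1 (N) and -1 (C) each, which
#' cancel per chain.
#' @return Named numeric vector of per-residue charges.
#' @export
default_charge_rules <- function() {
  c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0,
    HID = 0, HIE = 0, HIP = 1, ASH = 0, GLH = 0, LYN = 0, CYX = 0)
}

#' Net formal charge of a structure
#'
#' Residue-level charges from `rules`, one (+1, -1) terminus pair per
#' protein chain, and unit charges for monatomic ions already present
#' (Cl-, Br-, I-: -1; Na+, K+: +1; Mg2+, Ca2+, Zn2+: +2).
#'
#' @param s A `wat_structure`.
#' @param rules Named charge vector as in [default_charge_rules()].
#' @return Integer net charge.
#' @export
net_charge <- function(s, rules = default_charge_rules()) {
  if (!"atom_class" %in% names(s)) s <- suppressWarnings(classify_atoms(s))
  res <- s |>
    dplyr::filter(.data$atom_class %in%
                    c("main_chain", "side_chain_hydrophilic",
                      "side_chain_hydrophobic")) |>
    dplyr::distinct(.data$chain, .data$resid, .data$resname)
  q <- rules[toupper(res$resname)]
  q[is.na(q)] <- 0
  ion_q <- c(CL = -1, CLA = -1, `CL-` = -1, BR = -1, IOD = -1,
             `NA` = 1, SOD = 1, `NA+` = 1, K = 1,
             MG = 2, CA2 = 2, ZN = 2)
  ions <- s$resname[s$atom_class == "ion"]
  qi <- ion_q[toupper(ions)]
  qi[is.na(qi)] <- 0
  total <- sum(q) + sum(qi)  # termini +1/-1 cancel per chain
  if (abs(total - round(total)) > 1e-9) {
    stop("non-integer net charge from charge rules", call. = FALSE)
  }
  as.integer(round(total))
}

#' Neutralize a system with monatomic counterions
#'
#' Computes the net formal charge with [net_charge()] and adds that many
#' chloride (net positive) or sodium (net negative) ions at random
#' non-clashing positions. Idempotent: a neutral system gains no ions.
#'
#' @inheritParams insert_waters
#' @param rules Residue charge rules.
#' @return A `wat_structure` with total formal charge zero; the ion count
#'   added is recorded in its metadata as `n_counterions`.
#' @export
neutralize <- function(s, rules = default_charge_rules(), clash_cutoff = 2.4,
                       seed = 1L, max_attempts = 10000L) {
  q <- net_charge(s, rules)
  meta <- structure_metadata(s)
  meta$n_counterions <- abs(q)
  if (q == 0) {
    structure_metadata(s) <- meta
    return(s)
  }
  box <- structure_box(s)
  if (is.null(box)) stop("neutralize needs a periodic box", call. = FALSE)
  ion <- if (q > 0) list(resname = "CL", element = "CL")
         else list(resname = "NA", element = "NA")
  n <- abs(q)
  heavy <- coords(s)[toupper(s$element) != "H", , drop = FALSE]
  ids <- next_ids(s)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  pos <- matrix(0, 0, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- stats::runif(3) * box
      ref <- rbind(heavy, pos)
      if (nrow(ref) > 0 &&
          min(cross_dist(rbind(p), ref, box)) < clash_cutoff) next
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place counterion ", i, " of ", n, call. = FALSE)
    pos <- rbind(pos, p)
  }
  ions <- tibble::tibble(
    serial = ids$serial + seq_len(n) - 1L,
    name = ion$element, element = ion$element,
    resname = ion$resname, resid = ids$resid + seq_len(n) - 1L,
    chain = "I", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occupancy = 1, altloc = "")
  if ("atom_class" %in% names(s)) ions$atom_class <- "ion"
  new_structure(dplyr::bind_rows(tibble::as_tibble(s), ions),
                box = box, metadata = meta)
}
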