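# fixture builders and independent oracles shared across the suite

water_sites_at <- function(o, h1_dir, h2_dir, oh = 0.9572) {
  rbind(o, o + oh * h1_dir / sqrt(sum(h1_dir^2)),
        o + oh * h2_dir / sqrt(sum(h2_dir^2)))
}

# n waters as a structure; xyz is a (3n x 3) matrix ordered O,H1,H2
waters_from_xyz <- function(xyz, box = NULL, chain = "W", resid_start = 1L) {
  n <- nrow(xyz) / 3
  new_structure(tibble::tibble(
    serial = seq_len(3 * n),
    name = rep(c("O", "H1", "H2"), n),
    element = rep(c("O", "H", "H"), n),
    resname = "HOH",
    resid = rep(seq_len(n) + resid_start - 1L, each = 3L),
    chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]), box = box)
}

# collinear donor->acceptor dimer along +x; acceptor hydrogens point away
# (+x half-space) so only the donor O-H...O geometry is near-linear
water_dimer <- function(d_oo = 2.8) {
  a104 <- 104.52 * pi / 180
  don <- water_sites_at(c(0, 0, 0), c(1, 0, 0),
                        c(cos(a104), 0, sin(a104)))
  acc <- water_sites_at(c(d_oo, 0, 0), c(1, 0, 0),
                        c(cos(a104), 0, sin(a104)))
  waters_from_xyz(rbind(don, acc))
}

# n waters with random positions and orientations in a periodic cube
random_water_box <- function(n, edge, seed) {
  set.seed(seed)
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    o <- runif(3) * edge
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- rnorm(3); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    a104 <- 104.52 * pi / 180
    water_sites_at(o, u, cos(a104) * u + sin(a104) * v)
  }))
  waters_from_xyz(xyz, box = rep(edge, 3))
}

# independent minimum-image oracle: explicit minimum over 27 images
bf_min_image <- function(p, q, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p - (q + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# independent geometry oracle
bf_geometry <- function(d, h, a, box = NULL) {
  v1 <- d - h
  v2 <- a - h
  if (!is.null(box)) {
    v1 <- v1 - box * round(v1 / box)
    v2 <- v2 - box * round(v2 / box)
  }
  r <- sqrt(sum(v2^2))
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * r)
  c(r = r, theta = 180 - acos(max(-1, min(1, cosang))) * 180 / pi)
}

# brute-force water-water hydrogen-bond detection by explicit loops,
# independent of the package's vectorised path
bf_water_hbonds <- function(s, d_max = 3.5, theta_max = 60) {
  xyz <- as.matrix(s[, c("x", "y", "z")])
  box <- structure_box(s)
  o_idx <- which(s$name == "O")
  bonds <- list()
  for (i in o_idx) for (j in o_idx) {
    if (i == j) next
    doo <- if (is.null(box)) sqrt(sum((xyz[i, ] - xyz[j, ])^2)) else {
      bf_min_image(xyz[i, ], xyz[j, ], box)
    }
    if (doo >= d_max) next
    for (hh in i + 1:2) {  # O,H1,H2 layout
      g <- bf_geometry(xyz[i, ], xyz[hh, ], xyz[j, ], box)
      if (g["theta"] <= theta_max) {
        bonds[[length(bonds) + 1L]] <-
          c(donor = s$serial[i], hydrogen = s$serial[hh],
            acceptor = s$serial[j])
      }
    }
  }
  if (length(bonds) == 0) return(matrix(integer(), 0, 3))
  m <- do.call(rbind, bonds)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# all pairwise minimum-image distances via the 27-image oracle
cross_dist_oracle <- function(m, box) {
  n <- nrow(m)
  out <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    out <- c(out, bf_min_image(m[i, ], m[j, ], box))
  }
  out
}

# small protein-plus-water system for round trips and classification
toy_protein_system <- function() {
  atoms <- tibble::tribble(
    ~serial, ~name, ~element, ~resname, ~resid, ~chain, ~x, ~y, ~z,
    1L, "N",   "N", "SER", 1L, "A", 0.0, 0.0, 0.0,
    2L, "CA",  "C", "SER", 1L, "A", 1.4, 0.3, 0.1,
    3L, "C",   "C", "SER", 1L, "A", 2.1, 1.2, 0.0,
    4L, "O",   "O", "SER", 1L, "A", 1.9, 2.4, 0.2,
    5L, "OG",  "O", "SER", 1L, "A", 1.9, -1.0, 1.0,
    6L, "N",   "N", "LEU", 2L, "A", 3.3, 0.8, 0.1,
    7L, "CA",  "C", "LEU", 2L, "A", 4.3, 1.7, 0.3,
    8L, "CD1", "C", "LEU", 2L, "A", 5.9, 1.2, 2.1,
    9L, "O",   "O", "HOH", 10L, "W", 8.0, 8.0, 8.0,
    10L, "H1", "H", "HOH", 10L, "W", 8.8, 8.2, 8.4,
    11L, "H2", "H", "HOH", 10L, "W", 7.5, 8.7, 8.5,
    12L, "CL", "CL", "CL", 20L, "I", 12.0, 12.0, 12.0)
  new_structure(atoms, box = c(20, 25, 30))
}
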