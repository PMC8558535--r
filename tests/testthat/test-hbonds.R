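test_that("hydrogen-bond geometry matches the independent oracle", {
  g <- hb_geometry(c(0, 0, 0), c(0.96, 0, 0), c(2.8, 0, 0))
  expect_equal(g$r, 1.84)
  expect_equal(g$theta, 0)
  # O-H...O angle of 120 degrees at H...O = 2 A means theta = 60
  a <- c(0.96, 0, 0) + 2.0 * c(cos(pi / 3), sin(pi / 3), 0)
  g2 <- hb_geometry(c(0, 0, 0), c(0.96, 0, 0), a)
  expect_equal(g2$r, 2.0)
  expect_equal(g2$theta, 60, tolerance = 1e-9)
  expect_error(hb_geometry(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "degenerate")
  set.seed(7)
  box <- c(12, 12, 12)
  for (k in 1:50) {
    d <- runif(3) * box; h <- d + rnorm(3, sd = 0.5)
    a <- h + rnorm(3, sd = 1.5)
    got <- hb_geometry(d, h, a, box)
    want <- bf_geometry(d, h, a, box)
    expect_equal(got$r, unname(want["r"]), tolerance = 1e-9)
    expect_equal(got$theta, unname(want["theta"]), tolerance = 1e-9)
  }
})

test_that("bond criterion gates on distance (strict) and angle (inclusive)", {
  # interoxygen distance at exactly the cutoff is NOT bonded
  at_cut <- water_dimer(3.5)
  expect_equal(nrow(find_hbonds(classify_atoms(at_cut))), 0)
  expect_equal(nrow(find_hbonds(classify_atoms(water_dimer(3.6)))), 0)
  just_in <- water_dimer(3.5 - 1e-6)
  expect_equal(nrow(find_hbonds(classify_atoms(just_in))), 1)
  b <- find_hbonds(classify_atoms(water_dimer(2.8)))
  expect_equal(nrow(b), 1)
  expect_equal(b$theta, 0, tolerance = 1e-9)
  expect_equal(b$d_da, 2.8, tolerance = 1e-9)
  # an O-H...O angle of exactly 120 degrees (theta = 60) IS bonded
  a104 <- 104.52 * pi / 180
  don <- water_sites_at(c(0, 0, 0), c(1, 0, 0), c(cos(a104), 0, sin(a104)))
  acc_o <- c(0.9572, 0, 0) + 2.0 * c(cos(pi / 3), sin(pi / 3), 0)
  acc <- water_sites_at(acc_o, c(1, 0, 0), c(cos(a104), 0, sin(a104)))
  pair <- waters_from_xyz(rbind(don, acc))
  b2 <- find_hbonds(classify_atoms(pair))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$theta, 60, tolerance = 1e-6)
  # and just past it is not
  acc_o3 <- c(0.9572, 0, 0) + 2.0 * c(cos(pi / 3 + 0.02), sin(pi / 3 + 0.02), 0)
  acc3 <- water_sites_at(acc_o3, c(1, 0, 0), c(cos(a104), 0, sin(a104)))
  pair3 <- waters_from_xyz(rbind(don, acc3))
  expect_equal(nrow(find_hbonds(classify_atoms(pair3))), 0)
})

test_that("bond detection is symmetric under relabelling the dimer", {
  d <- water_dimer(2.8)
  flipped <- new_structure(d[c(4:6, 1:3), ], box = structure_box(d))
  flipped$serial <- 1:6
  b1 <- find_hbonds(classify_atoms(d))
  b2 <- find_hbonds(classify_atoms(flipped))
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(sort(c(b1$r, b1$theta)), sort(c(b2$r, b2$theta)),
               tolerance = 1e-9)
})

test_that("structures without hydrogens raise an explicit error", {
  bare <- new_structure(tibble::tibble(
    serial = 1:2, name = "O", element = "O", resname = "HOH",
    resid = 1:2, chain = "W", x = c(0, 2.8), y = 0, z = 0))
  expect_error(find_hbonds(classify_atoms(bare)), "hydrogens")
})

test_that("vectorised detection equals brute force on random water boxes", {
  for (seed in 1:20) {
    s <- classify_atoms(random_water_box(64, 12, seed = seed))
    got <- find_hbonds(s)
    got_m <- as.matrix(got[, c("donor_serial", "hydrogen_serial",
                               "acceptor_serial")])
    got_m <- got_m[order(got_m[, 1], got_m[, 2], got_m[, 3]), , drop = FALSE]
    want <- bf_water_hbonds(s)
    expect_equal(unname(got_m), unname(want))
  }
})

test_that("per-water bond counts decompose by partner class", {
  # dilute gas: no bonds at all
  far <- waters_from_xyz(rbind(
    water_sites_at(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    water_sites_at(c(8, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    water_sites_at(c(0, 8, 0), c(1, 0, 0), c(0, 1, 0))))
  pw <- per_water_counts(classify_atoms(far))
  expect_equal(pw$total, 0)
  # constructed fixture: W1 donates to W2 and to a carbonyl O; W2 donates
  # to a second carbonyl O. Hand count: each water has 1 water-water and
  # 1 water-protein bond.
  w1 <- water_sites_at(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  w2 <- water_sites_at(c(2.8, 0, 0), c(0, 1, 0), c(0, 0, 1))
  wat <- waters_from_xyz(rbind(w1, w2))
  prot <- tibble::tibble(
    serial = 7:8, name = "O", element = "O", resname = "GLY",
    resid = 3:4, chain = "A",
    x = c(0, 2.8), y = c(2.8, 2.8), z = 0)
  s <- classify_atoms(new_structure(dplyr::bind_rows(
    tibble::as_tibble(wat), prot)))
  pw2 <- per_water_counts(s)
  expect_equal(pw2$total, 2.0)
  expect_equal(pw2$water_water, 1.0)
  expect_equal(pw2$water_protein, 1.0)
  expect_equal(pw2$water_main_chain, 1.0)
  expect_equal(pw2$water_side_chain, 0.0)
  # decomposition identities
  expect_equal(pw2$water_water + pw2$water_protein, pw2$total)
  expect_equal(pw2$water_main_chain + pw2$water_side_chain,
               pw2$water_protein)
  expect_error(per_water_counts(classify_atoms(toy_protein_system()[1:8, ])),
               "no water")
})

test_that("ideal and jittered ice lattices recover the bulk bond count", {
  ice <- make_ice_lattice(3, jitter_sigma = 0, seed = 1)
  pw <- per_water_counts(ice)
  expect_equal(pw$total, 4.0)
  expect_equal(pw$water_water, 4.0)
  jit <- make_ice_lattice(3, jitter_sigma = 0.1, seed = 2)
  pwj <- per_water_counts(jit)
  expect_gte(pwj$total, 3.9)
  expect_lte(pwj$total, 4.1)
})

test_that("the water network collapses parallel bonds and drops protein", {
  expect_equal(igraph::vcount(water_network(find_hbonds(
    classify_atoms(water_dimer(5))))), 0)
  b <- find_hbonds(classify_atoms(water_dimer(2.8)))
  g <- water_network(b)
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  # edge count never exceeds the water-water bond count
  s <- classify_atoms(random_water_box(64, 12, seed = 3))
  bonds <- find_hbonds(s)
  ww <- sum(bonds$donor_class == "water" & bonds$acceptor_class == "water")
  expect_lte(igraph::ecount(water_network(bonds)), ww)
})

test_that("ring perception finds minimal cycles once each", {
  ring5 <- igraph::make_ring(5)
  igraph::V(ring5)$name <- paste0("w", 1:5)
  r <- find_rings(ring5)
  expect_equal(nrow(r), 1)
  expect_equal(r$size, 5)
  tree <- igraph::make_tree(7, children = 2, mode = "undirected")
  igraph::V(tree)$name <- paste0("t", 1:7)
  expect_equal(nrow(find_rings(tree)), 0)
  # cube graph: every minimal cycle is a 4-cycle face; exhaustive
  # enumeration oracle counts distinct 4-cycles
  cube <- igraph::make_graph("Cubical")
  igraph::V(cube)$name <- paste0("c", 1:8)
  r4 <- find_rings(cube, max_size = 6)
  expect_true(all(r4$size == 4))
  adj <- igraph::as_adjacency_matrix(cube, sparse = FALSE)
  n4 <- 0
  combs <- utils::combn(8, 4)
  for (k in seq_len(ncol(combs))) {
    v <- combs[, k]
    perms <- rbind(c(1, 2, 3, 4), c(1, 2, 4, 3), c(1, 3, 2, 4))
    for (p in seq_len(nrow(perms))) {
      w <- v[perms[p, ]]
      if (adj[w[1], w[2]] && adj[w[2], w[3]] && adj[w[3], w[4]] &&
          adj[w[4], w[1]]) {
        n4 <- n4 + 1
      }
    }
  }
  expect_equal(nrow(r4), n4)
})

test_that("ring fixtures close into a single n-ring near a surface", {
  ring <- make_ring_fixture(5)
  bonds <- find_hbonds(classify_atoms(ring))
  rings <- find_rings(water_network(bonds))
  expect_equal(nrow(rings), 1)
  expect_equal(rings$size, 5)
  # stretched triangle: distance gate kills every bond
  none <- make_ring_fixture(3, o_o = 8.0)
  expect_equal(nrow(find_hbonds(classify_atoms(none))), 0)
  rings6 <- find_rings(water_network(find_hbonds(
    classify_atoms(make_ring_fixture(6)))))
  expect_equal(rings6$size, 6)
})

test_that("rings are kept only near the requested class", {
  ring <- make_ring_fixture(5)
  slab <- tibble::tibble(
    serial = 100:103, name = "CD1", element = "C", resname = "LEU",
    resid = 100:103, chain = "P",
    x = c(-2, 2, -2, 2), y = c(-2, -2, 2, 2), z = -3)
  s <- classify_atoms(new_structure(dplyr::bind_rows(
    tibble::as_tibble(ring), slab)))
  bonds <- find_hbonds(s)
  rings <- find_rings(water_network(bonds))
  near <- rings_near_class(rings, s, "side_chain_hydrophobic", cutoff = 4)
  expect_equal(nrow(near), 1)
  far <- rings_near_class(rings, s, "side_chain_hydrophobic", cutoff = 0.5)
  expect_equal(nrow(far), 0)
  expect_error(rings_near_class(rings, s, "greasy"), "unknown")
  expect_true(all(near$ring_id %in% rings$ring_id))
})
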