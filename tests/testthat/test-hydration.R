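test_that("surface-distance profile bins constructed waters correctly", {
  s <- make_toy_surface(1, 0)
  p <- surface_distance_profile(s)
  at_hb <- function(cls) {
    p$count[p$class == cls & p$bin_lo <= 1.8 & p$bin_hi > 1.8]
  }
  expect_equal(at_hb("main_chain"), 1)
  expect_equal(at_hb("whole_surface"), 1)
  expect_equal(sum(p$count[p$class == "whole_surface"]), 1)
  expect_equal(sum(p$count[p$class == "side_chain_hydrophobic"]), 0)
  # vdw-site waters land in the 2.5 A bin of the hydrophobic profile
  s2 <- make_toy_surface(5, 7)
  p2 <- surface_distance_profile(s2)
  expect_equal(p2$count[p2$class == "side_chain_hydrophobic" &
                          p2$bin_lo <= 2.5 & p2$bin_hi > 2.5], 7)
  expect_equal(p2$count[p2$class == "main_chain" &
                          p2$bin_lo <= 1.8 & p2$bin_hi > 1.8], 5)
  # no waters -> all-zero profile
  dry <- classify_atoms(toy_protein_system())
  dry <- new_structure(dry[dry$atom_class != "water", ],
                       box = structure_box(dry))
  expect_equal(sum(surface_distance_profile(dry)$count), 0)
  expect_error(surface_distance_profile(s, r_max = -1), "positive")
})

test_that("profile counts match a brute-force minimum-distance oracle", {
  set.seed(5)
  prot <- classify_atoms(toy_protein_system())
  prot <- new_structure(prot[prot$atom_class != "ion", ],
                        box = c(20, 25, 30))
  wat <- random_water_box(20, 18, seed = 9)
  wt <- tibble::as_tibble(wat)
  wt$serial <- wt$serial + 100L
  wt$resid <- wt$resid + 100L
  s <- classify_atoms(new_structure(
    dplyr::bind_rows(tibble::as_tibble(prot), wt), box = c(20, 25, 30)))
  p <- surface_distance_profile(s, bin_width = 0.25, r_max = 8)
  # oracle: explicit minimum over protein atoms per water oxygen
  xyz <- as.matrix(s[, c("x", "y", "z")])
  box <- structure_box(s)
  prot_idx <- which(s$atom_class %in% c("main_chain",
                                        "side_chain_hydrophilic",
                                        "side_chain_hydrophobic"))
  wo_idx <- which(s$atom_class == "water" & s$element == "O")
  dmin <- vapply(wo_idx, function(i) {
    min(vapply(prot_idx, function(j) bf_min_image(xyz[i, ], xyz[j, ], box),
               numeric(1)))
  }, numeric(1))
  edges <- seq(0, 8, by = 0.25)
  want <- as.numeric(table(cut(dmin[dmin < 8], edges, right = FALSE)))
  got <- p$count[p$class == "whole_surface"]
  expect_equal(got, want)
  # conservation: in-range waters equal the histogram mass
  expect_equal(sum(got), sum(dmin < 8))
})

test_that("the geometry map scores a collinear dimer into one bin", {
  m <- geometry_map(water_dimer(2.8))
  gl <- glance(m)
  expect_equal(gl$n_binned, 1)
  expect_equal(gl$peak_r, 1.85)  # bin [1.8, 1.9) holds r = 1.843
  expect_equal(gl$peak_theta, 2.5)
  expect_equal(sum(m$count), 1)
  # far-apart waters give an all-zero map and map_peak refuses it
  m0 <- geometry_map(water_dimer(6))
  expect_equal(sum(m0$count), 0)
  expect_error(map_peak(m0), "empty")
})

test_that("map counts reconcile with bond detection under the criterion", {
  s <- classify_atoms(random_water_box(64, 12, seed = 21))
  m <- geometry_map(s, r_edges = seq(0, 5, 0.1),
                    theta_edges = seq(0, 90, 5))
  bonds <- find_hbonds(s, pairs = "water_water")
  expect_equal(sum(m$count[m$theta_center < 60]), nrow(bonds))
  # conservation: binned + spilled = scored
  expect_equal(sum(m$count) + attr(m, "spill"), attr(m, "n_scored"))
})

test_that("geometry maps are invariant to frame order and rigid motion", {
  s1 <- random_water_box(32, 10, seed = 31)
  s2 <- random_water_box(32, 10, seed = 32)
  # strip the box so rigid motion is exact (no wrapping involved)
  structure_box(s1) <- NULL
  structure_box(s2) <- NULL
  t12 <- new_trajectory(s1, list(coords(s1), coords(s2)))
  t21 <- new_trajectory(s1, list(coords(s2), coords(s1)))
  m12 <- geometry_map(t12)
  expect_equal(m12$count, geometry_map(t21)$count)
  ang <- 0.7
  rot <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  moved <- new_trajectory(s1, lapply(t12$coords, function(m) {
    t(rot %*% t(m)) + 5
  }))
  expect_equal(geometry_map(moved)$count, m12$count, tolerance = 1e-9)
})

test_that("map peaks break ties toward smaller r then smaller theta", {
  m <- geometry_map(water_dimer(2.8))
  m$count[] <- 0
  m$count[m$r_center == 2.05 & m$theta_center == 17.5] <- 5
  expect_equal(map_peak(m)$r, 2.05)
  expect_equal(map_peak(m)$theta, 17.5)
  m$count[m$r_center == 1.45 & m$theta_center == 32.5] <- 5
  m$count[m$r_center == 1.45 & m$theta_center == 12.5] <- 5
  pk <- map_peak(m)
  expect_equal(pk$r, 1.45)
  expect_equal(pk$theta, 12.5)
})

test_that("peak trends scale linearly and demand distinct levels", {
  p1 <- surface_distance_profile(make_toy_surface(2, 3), h = 0.1)
  p2 <- p1
  p2$count <- p1$count * 2
  p2$h <- 0.2
  tr <- peak_trends(list(p1, p2))
  v1 <- tr$value[tr$h == 0.1]
  v2 <- tr$value[tr$h == 0.2]
  expect_equal(v2, 2 * v1)
  expect_equal(nrow(peak_trends(list(p1))),
               2 * length(unique(p1$class)))
  expect_error(peak_trends(list(p1, p1)), "duplicated")
  # monotone fixture series gives nondecreasing trends
  series <- lapply(1:3, function(k) {
    surface_distance_profile(make_toy_surface(2 * k, 3 * k), h = 0.1 * k)
  })
  tr3 <- peak_trends(series)
  for (cls in c("main_chain", "side_chain_hydrophobic")) {
    for (d in c("hb", "vdw")) {
      v <- tr3$value[tr3$class == cls & tr3$distance == d]
      expect_true(all(diff(v) >= 0))
    }
  }
})

test_that("contact maps are symmetric under chain swap", {
  s <- classify_atoms(toy_protein_system())
  prot <- new_structure(s[s$atom_class != "water" & s$atom_class != "ion", ],
                        box = c(25, 25, 30))
  four <- apply_space_group(prot, "P41", c(25, 25, 30))
  cm <- contact_map(four, "A", "B", cutoff = 6)
  expect_s3_class(cm, "wat_contact_map")
  cm_t <- contact_map(four, "B", "A", cutoff = 6)
  merged <- dplyr::inner_join(
    tibble::as_tibble(cm), tibble::as_tibble(cm_t),
    by = c(resid_a = "resid_b", resid_b = "resid_a"))
  expect_equal(merged$contact.x, merged$contact.y)
  expect_equal(merged$dmin.x, merged$dmin.y, tolerance = 1e-9)
  expect_error(contact_map(four, "A", "A"), "differ")
  # residues a hair under the cutoff are contacts; far chains are not
  two <- new_structure(tibble::tibble(
    serial = 1:2, name = "CA", element = "C", resname = "GLY",
    resid = c(1L, 2L), chain = c("A", "B"),
    x = c(0, 3.9), y = 0, z = 0), box = c(200, 200, 200))
  expect_true(all(contact_map(two, "A", "B", cutoff = 4.5)$contact))
  two$x[2] <- 50
  expect_false(any(contact_map(two, "A", "B", cutoff = 4.5)$contact))
})
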