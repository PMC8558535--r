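# an entry tibble straight from in-memory structures (no files needed)
entries_from <- function(...) {
  specs <- list(...)
  tibble::tibble(
    entry_id = vapply(specs, `[[`, character(1), "id"),
    method = vapply(specs, `[[`, character(1), "method"),
    resolution = vapply(specs, function(x) x$resolution, numeric(1)),
    structure = lapply(specs, `[[`, "structure"))
}

test_that("entry filtering keeps good neutron data and drops the rest", {
  d <- water_dimer(2.8)
  e <- entries_from(
    list(id = "N15", method = "neutron", resolution = 1.5, structure = d),
    list(id = "N25", method = "neutron", resolution = 2.5, structure = d),
    list(id = "X10", method = "xray", resolution = 1.0, structure = d))
  kept <- filter_entries(e)
  expect_equal(kept$entry_id, "N15")
  # boundary: resolution exactly 2.0 is still acceptable quality
  e2 <- entries_from(
    list(id = "N20", method = "neutron", resolution = 2.0, structure = d))
  expect_equal(nrow(filter_entries(e2)), 1)
  # entries with missing metadata are dropped, with a message
  e3 <- e
  e3$resolution[1] <- NA
  expect_message(k3 <- filter_entries(e3), "missing")
  expect_equal(nrow(k3), 0)
  expect_equal(nrow(filter_entries(e[0, ])), 0)
  # ten-entry mixed fixture against a hand-applied filter
  set.seed(13)
  methods <- sample(c("neutron", "xray"), 10, replace = TRUE)
  res <- round(runif(10, 0.8, 3.0), 2)
  e10 <- tibble::tibble(entry_id = paste0("E", 1:10), method = methods,
                        resolution = res,
                        structure = replicate(10, d, simplify = FALSE))
  want <- e10$entry_id[methods == "neutron" & res <= 2.0]
  expect_equal(filter_entries(e10)$entry_id, want)
})

test_that("crystal geometry maps are additive and bin constructed cases", {
  d <- water_dimer(2.8)
  e1 <- entries_from(
    list(id = "A", method = "neutron", resolution = 1.5, structure = d))
  m1 <- crystal_geometry_map(e1)
  expect_equal(sum(m1$count), 1)
  pk <- map_peak(m1)
  expect_equal(pk$r, 1.85)   # bin [1.8, 1.9) holds 2.8 - 0.9572
  expect_equal(pk$theta, 2.5)
  # the same entry twice doubles every bin exactly
  e2 <- entries_from(
    list(id = "A", method = "neutron", resolution = 1.5, structure = d),
    list(id = "B", method = "neutron", resolution = 1.5, structure = d))
  m2 <- crystal_geometry_map(e2)
  expect_equal(m2$count, 2 * m1$count)
  # bent water pair at r = 2.5, theta = 55 lands in that bin
  a104 <- 104.52 * pi / 180
  don <- water_sites_at(c(0, 0, 0), c(1, 0, 0),
                        c(cos(a104), 0, sin(a104)))
  u <- c(cos(55 * pi / 180), sin(55 * pi / 180), 0)
  acc_o <- c(0.9572, 0, 0) + 2.5 * u
  acc <- water_sites_at(acc_o, u, c(u[1] * cos(a104) - u[2] * sin(a104),
                                    u[1] * sin(a104) + u[2] * cos(a104), 0))
  bent <- waters_from_xyz(rbind(don, acc))
  mb <- crystal_geometry_map(entries_from(
    list(id = "C", method = "neutron", resolution = 1.9, structure = bent)))
  hit <- mb$count[mb$r_center > 2.5 & mb$r_center < 2.6 &
                    mb$theta_center > 55 & mb$theta_center < 60]
  expect_equal(hit, 1)
})

test_that("waters without hydrogens are skipped, not fabricated", {
  dry <- new_structure(tibble::tibble(
    serial = 1:2, name = "O", element = "O", resname = "HOH",
    resid = 1:2, chain = "W", x = c(0, 2.8), y = 0, z = 0))
  wet <- water_dimer(2.8)
  mixed <- new_structure(dplyr::bind_rows(
    tibble::as_tibble(wet),
    tibble::tibble(serial = 7:8, name = "O", element = "O",
                   resname = "HOH", resid = 7:8, chain = "X",
                   x = c(20, 22.8), y = 20, z = 20)))
  e <- entries_from(
    list(id = "M", method = "neutron", resolution = 1.5, structure = mixed))
  m <- crystal_geometry_map(e)
  expect_equal(attr(m, "skipped_waters"), 2)
  expect_error(crystal_geometry_map(entries_from(
    list(id = "D", method = "neutron", resolution = 1.5, structure = dry))),
    "no scorable|hydrogens")
})

test_that("symmetry expansion is a no-op for P1 entries", {
  d <- water_dimer(2.8)
  structure_box(d) <- c(20, 20, 20)
  structure_metadata(d) <- list(space_group = "P 1")
  e <- entries_from(
    list(id = "P", method = "neutron", resolution = 1.5, structure = d))
  m_direct <- crystal_geometry_map(e, expand_symmetry = FALSE)
  m_sym <- crystal_geometry_map(e, expand_symmetry = TRUE)
  expect_equal(m_sym$count, m_direct$count)
})

test_that("entry sets round-trip through files and the manifest", {
  d <- water_dimer(2.8)
  structure_box(d) <- c(20, 20, 20)
  out <- withr::local_tempdir()
  spec <- tibble::tibble(
    entry_id = c("n15", "n25", "x10"),
    method = c("neutron", "neutron", "xray"),
    resolution = c(1.5, 2.5, 1.0),
    structure = list(d, d, d))
  manifest <- make_fixture_entry_set(spec, out)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  entries <- read_entry_set(file.path(out, "manifest.csv"), out)
  expect_equal(nrow(entries), 3)
  expect_equal(nrow(filter_entries(entries)), 1)
  back <- entries$structure[[1]]
  expect_lt(max(abs(coords(back) - coords(d))), 1e-3)
  expect_error(make_fixture_entry_set(spec[c(1, 1), ], out), "duplicate")
  empty <- make_fixture_entry_set(spec[0, ], out)
  expect_equal(nrow(empty), 0)
})
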