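test_that("PDB and mmCIF fixtures load with identical coordinates", {
  pdb <- load_model(extdata("fixture_model.pdb"))
  expect_identical(nrow(pdb), 5L)
  expect_equal(pdb$x[1], 1.5)
  expect_equal(pdb$z[5], 23.5)
  expect_identical(pdb$atom[5], "O1")
  expect_identical(pdb$resid[5], "Q1C")

  cif <- load_model(extdata("fixture_model.cif"))
  expect_identical(nrow(cif), 5L)
  expect_equal(cif[, c("x", "y", "z")], pdb[, c("x", "y", "z")],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_identical(cif$atom, pdb$atom)

  empty <- withr::local_tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(load_model(empty), "empty")
  expect_error(load_model("no/such/file.pdb"), "not found")
})

test_that("written PDB models round-trip through load_model", {
  m <- make_fixture_model(model_fixture_spec(lattice_extent = 24,
                                             jitter_sigma = 1.5, seed = 4))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(m, path)
  back <- load_model(path)
  expect_identical(nrow(back), nrow(m))
  expect_equal(back$x, m$x, tolerance = 1e-3)
  expect_equal(back$z, m$z, tolerance = 1e-3)
  expect_identical(back$atom[nrow(back)], "O1")
})

test_that("selection expressions filter conjunctively and by radius", {
  m <- load_model(extdata("fixture_model.pdb"))
  expect_identical(nrow(select_atoms(m, elem = "P")), 3L)
  expect_identical(nrow(select_atoms(m, chain = "L", atom = "C1")), 1L)
  expect_identical(nrow(select_atoms(m, chain = "Q", elem = "P")), 0L)
  near <- select_atoms(m, within = list(radius = 5, of = c(0, 0, 3.5)))
  expect_identical(nrow(near), 2L)   # P at (1.5,2.5) and P at (-4.25,0)
})

test_that("membrane height matches the fixture's exact ground truth", {
  m0 <- make_fixture_model(model_fixture_spec(jitter_sigma = 0,
                                              head_plane_z = 0))
  h <- membrane_height(m0)
  expect_identical(h$kind, "membrane_height")
  expect_equal(h$value, 0)

  # jittered case: SEM-scale agreement
  mj <- make_fixture_model(model_fixture_spec(lattice_extent = 80,
                                              lattice_spacing = 8,
                                              jitter_sigma = 2, seed = 9))
  hj <- membrane_height(mj)
  expect_lt(abs(hj$value), 0.3)
  expect_gte(hj$n_atoms_used, 400)

  # a radius that excludes every atom errors
  expect_error(membrane_height(m0, region_centre = c(1e4, 1e4, 0),
                               radius = 10), "no headgroup atoms")
})

test_that("m_distance reproduces the constructed ligand heights exactly", {
  for (hgt in c(0, 20, -7.5)) {
    m <- make_fixture_model(model_fixture_spec(jitter_sigma = 0,
                                               ligand_height = hgt))
    h <- membrane_height(m)
    lig <- select_atoms(m, resid = "Q1C")
    md <- m_distance(m, lig, h)
    expect_equal(md$value, hgt)
  }
  # centroid fallback when the reference atom is absent
  m <- make_fixture_model(model_fixture_spec(jitter_sigma = 0,
                                             ligand_height = 20))
  lig <- select_atoms(m, resid = "Q1C")
  lig$atom <- "O9"
  md <- m_distance(m, lig, membrane_height(m))
  expect_equal(md$value, 20)
  expect_error(m_distance(m, lig[0, ], membrane_height(m)), "empty")
})

test_that("e_distance is a plain Euclidean distance to the landmark", {
  m <- make_fixture_model(model_fixture_spec(jitter_sigma = 0,
                                             ligand_height = 0))
  lig <- select_atoms(m, resid = "Q1C")
  expect_equal(e_distance(m, lig, c(0, 0, 0))$value, 0)
  lig$x <- 3; lig$y <- 4; lig$z <- 0
  expect_equal(e_distance(m, lig, c(0, 0, 0))$value, 5)
  # translation invariance
  lig2 <- lig; lig2$x <- lig2$x + 11; lig2$y <- lig2$y - 3; lig2$z <- lig2$z + 6
  expect_equal(e_distance(m, lig2, c(11, -3, 6))$value, 5)
})

test_that("group_distance matches a brute-force pairwise oracle", {
  brute_min <- function(A, B) {
    best <- Inf
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    best
  }
  m <- make_fixture_model(model_fixture_spec())
  for (seed in 1:10) {
    set.seed(seed)
    A <- matrix(runif(45, -30, 30), ncol = 3)
    B <- matrix(runif(60, -30, 30), ncol = 3)
    sa <- structure_model(data.frame(elem = "C", atom = "C1", resid = "LIG",
                                     resno = 1, chain = "A", x = A[, 1],
                                     y = A[, 2], z = A[, 3], occ = 1))
    sb <- structure_model(data.frame(elem = "C", atom = "C1", resid = "LIG",
                                     resno = 2, chain = "B", x = B[, 1],
                                     y = B[, 2], z = B[, 3], occ = 1))
    gd <- group_distance(m, sa, sb, mode = "min")
    expect_equal(gd$value, brute_min(A, B), tolerance = 1e-12)
    gc_ <- group_distance(m, sa, sb, mode = "centroid")
    expect_equal(gc_$value, sqrt(sum((colMeans(A) - colMeans(B))^2)),
                 tolerance = 1e-12)
  }
  # identical selections: min distance 0
  expect_equal(group_distance(m, sa, sa, mode = "min")$value, 0)
  # 3-4-5 sanity in both modes
  one <- function(p) structure_model(data.frame(
    elem = "C", atom = "C1", resid = "LIG", resno = 1, chain = "A",
    x = p[1], y = p[2], z = p[3], occ = 1))
  expect_equal(group_distance(m, one(c(0, 0, 0)), one(c(1, 2, 2)))$value, 3)
  expect_error(group_distance(m, sa[0, ], sb), "empty")
})

test_that("distance measurements are invariant under joint rigid motions", {
  m <- make_fixture_model(model_fixture_spec(jitter_sigma = 1, seed = 6,
                                             ligand_height = 14))
  lig <- select_atoms(m, resid = "Q1C")
  p <- select_atoms(m, elem = "P")
  d0 <- group_distance(m, lig, p, mode = "min")$value
  e0 <- e_distance(m, lig, c(5, -2, 30))$value
  for (seed in 1:5) {
    R <- random_rotation(seed)
    t <- c(12, -70, 33)
    mt <- transform_model(m, R, t)
    ligt <- select_atoms(mt, resid = "Q1C")
    pt <- select_atoms(mt, elem = "P")
    expect_equal(group_distance(mt, ligt, pt, mode = "min")$value, d0,
                 tolerance = 1e-6)
    landmark <- as.vector(R %*% c(5, -2, 30) + t)
    expect_equal(e_distance(mt, ligt, landmark)$value, e0, tolerance = 1e-6)
  }
})

test_that("measurement results validate their invariants", {
  expect_error(measurement_result("e_distance", -1, 2), "distance")
  r <- measurement_result("m_distance", -3.5, 10, frame = "z-aligned")
  expect_equal(r$value, -3.5)
  df_path <- withr::local_tempfile(fileext = ".tsv")
  write_measurements_tsv(list(r), df_path, model_name = "fixture")
  back <- read_measurements_tsv(df_path)
  expect_identical(nrow(back), 1L)
  expect_equal(back$value_A, -3.5)
  expect_identical(back$model, "fixture")
})
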