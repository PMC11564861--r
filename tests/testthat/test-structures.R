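test_that("XYZ files round-trip and malformed files are rejected", {
  g <- toy_urea_fixture()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, path, comment = "toy")
  back <- read_xyz(path)
  expect_identical(back$atoms, g$atoms)
  expect_equal(back$coordinates, g$coordinates, tolerance = 1e-6)
  # write(read(f)) == read(f)
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(back, path2, comment = "toy")
  expect_equal(read_xyz(path2)$coordinates, back$coordinates,
               tolerance = 1e-12)

  writeLines(c("2", "two atoms", "H 0 0 0", "H 1 0 0"), path)
  expect_equal(length(read_xyz(path)$atoms), 2)
  writeLines(c("3", "count mismatch", "H 0 0 0", "H 1 0 0"), path)
  expect_error(read_xyz(path), "count")
  writeLines(c("2", "bad element", "H 0 0 0", "Xx 1 0 0"), path)
  expect_error(read_xyz(path), "unknown element")
  writeLines(c("2", "bad coord", "H 0 0 0", "H a 0 0"), path)
  expect_error(read_xyz(path), "row 4")
})

test_that("rotational constants from geometry match hand calculations", {
  # two unit masses 1 A apart: I = 0.5 amu A^2 about the axis
  g <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(1, 1))
  r <- constants_from_geometry(g)
  expect_true(is.infinite(r$constants[["A"]]))
  expect_equal(unname(r$constants[["B"]]), 505379.07 / 0.5, tolerance = 1e-9)
  expect_equal(r$constants[["B"]], r$constants[["C"]])

  # planar geometry: Ic = Ia + Ib
  gt <- toy_urea_fixture()
  rt <- constants_from_geometry(gt)
  expect_equal(rt$moments[["Ic"]], rt$moments[["Ia"]] + rt$moments[["Ib"]],
               tolerance = 1e-6)
  expect_true(rt$constants[["A"]] >= rt$constants[["B"]] &&
                rt$constants[["B"]] >= rt$constants[["C"]])

  # scaling all coordinates by 2 divides every constant by 4
  g2 <- geometry(gt$atoms, gt$coordinates * 2, masses = gt$masses)
  r2 <- constants_from_geometry(g2)
  expect_equal(unclass(r2$constants), unclass(rt$constants) / 4,
               tolerance = 1e-12)
})

test_that("constants are invariant under rigid rotation and translation", {
  gt <- toy_urea_fixture()
  rt <- constants_from_geometry(gt)
  th <- 0.73; ph <- 1.21
  R1 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3)
  xyz <- sweep(gt$coordinates %*% t(R2 %*% R1), 2, c(-3.2, 5.5, 0.1))
  rrot <- constants_from_geometry(geometry(gt$atoms, xyz, masses = gt$masses))
  expect_equal(unclass(rrot$constants), unclass(rt$constants),
               tolerance = 1e-6 / 1000)
  # and the asymmetry parameter carries over consistently
  expect_equal(asymmetry_kappa(rrot$constants), asymmetry_kappa(rt$constants),
               tolerance = 1e-9)
})

test_that("dipoles rotate into the principal frame with preserved norm", {
  gt <- toy_urea_fixture()
  expect_equal(unname(unclass(dipole_in_principal_axes(gt, c(0, 0, 0)))),
               c(0, 0, 0))
  set.seed(4)
  for (i in 1:5) {
    v <- stats::rnorm(3)
    mu <- dipole_in_principal_axes(gt, v)
    expect_equal(sqrt(sum(unclass(mu)^2)), sqrt(sum(v^2)), tolerance = 1e-9)
    expect_true(all(unclass(mu) >= 0))
  }
  # a vector along the a axis comes back as (|mu|, 0, 0)
  ax <- constants_from_geometry(gt)$axes
  mu_a <- dipole_in_principal_axes(gt, 2.5 * ax[1, ])
  expect_equal(unname(unclass(mu_a)), c(2.5, 0, 0), tolerance = 1e-9)
})

test_that("conformer matching reproduces the published identifications", {
  tab <- dulcin_conformers()
  m1 <- match_conformers(rot1_constants(), tab,
                         observed_types = c("a", "c"))
  expect_identical(m1$best, "II")
  expect_equal(unname(m1$scale_factors),
               c(3052.1532 / 3068, 304.82621 / 304, 292.43629 / 290),
               tolerance = 1e-9)
  expect_equal(unname(round(m1$scale_factors, 4)), c(0.9948, 1.0027, 1.0084))

  m2 <- match_conformers(rot2_constants(), tab, observed_types = "a")
  expect_identical(m2$best, "IV")

  # experimental equal to a candidate's theory: ratios exactly 1
  m3 <- match_conformers(rotational_constants(tab$A[3], tab$B[3], tab$C[3]),
                         tab)
  expect_identical(m3$best, "III")
  expect_equal(unname(m3$scale_factors), c(1, 1, 1))
  expect_error(match_conformers(rot1_constants(), tab[0, ]), "empty")
})

test_that("conformer matching is scale-consistent", {
  tab <- dulcin_conformers()
  s <- 1.004
  tab2 <- tab
  tab2[tab2$id == "II", c("A", "B", "C")] <-
    tab2[tab2$id == "II", c("A", "B", "C")] * s
  m <- match_conformers(rot1_constants(), tab)
  m2 <- match_conformers(rot1_constants(), tab2)
  ii <- which(tab$id == "II")
  expect_equal(as.numeric(m2$candidates[ii, c("A", "B", "C")]),
               as.numeric(m$candidates[ii, c("A", "B", "C")]) / s,
               tolerance = 1e-12)
})

test_that("glucophore triangles classify distances against the 2.5-4 A window", {
  # constructed three-site geometries
  g_in <- geometry(c("N", "H", "O", "C"),
                   rbind(c(0, 0, 0), c(1.0, 0, 0), c(3.0, 0, 0), c(0, 4, 0)))
  tri <- glucophore_triangle(g_in, AH = c(1, 2), B = 3, gamma = 4)
  expect_true(tri$compliant)
  expect_equal(tri$d_AH_B, 3.0)
  g_out <- geometry(c("N", "H", "O", "C"),
                    rbind(c(0, 0, 0), c(1.0, 0, 0), c(5.0, 0, 0), c(0, 4, 0)))
  expect_false(glucophore_triangle(g_out, c(1, 2), 3, 4)$compliant)

  # toy urea fragment: intramolecular N...O around 2.2-2.4 A, below the window
  gt <- toy_urea_fixture()
  tu <- glucophore_triangle(gt, AH = c(11, 12), B = 10, gamma = 1:6)
  expect_gt(tu$d_AH_B, 2.2)
  expect_lt(tu$d_AH_B, 2.4)
  expect_false(tu$compliant)
  # gamma as ring centroid is reproducible to high precision
  tu2 <- glucophore_triangle(gt, AH = c(11, 12), B = 10, gamma = 1:6)
  expect_identical(tu$d_B_gamma, tu2$d_B_gamma)

  expect_error(glucophore_triangle(gt, AH = c(11, 1), B = 10, gamma = 1:6),
               "not bonded")
  expect_error(glucophore_triangle(gt, AH = c(11, 12), B = 11, gamma = 11),
               "degenerate|coincident")
})

test_that("conformer tables read and write through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_conformer_table(dulcin_conformers(), path)
  back <- read_conformer_table(path)
  expect_equal(back, dulcin_conformers())
  writeLines("id\tA\tB", path)
  expect_error(read_conformer_table(path), "columns")
})
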