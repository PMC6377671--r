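write_toy_pdb <- function(lines) {
  path <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("hand-written PDB records parse with expected coordinates", {
  path <- write_toy_pdb(c(
    "ATOM      1  O1  LIG A   1       0.000   0.000   0.000  1.00  0.00           O",
    "ATOM      2  H1  LIG A   1       0.000   0.000   0.970  1.00  0.00           H",
    "ATOM      3  C1  LIG A   1       1.200   0.000  -0.500  1.00  0.00           C",
    "END"
  ))
  s <- read_structure(path)
  expect_equal(nrow(s), 3)
  expect_equal(s$element, c("O", "H", "C"))
  expect_equal(s$z, c(0, 0.97, -0.5))
})

test_that("elements fall back to the atom-name field", {
  path <- write_toy_pdb(c(
    "ATOM      1  CA1 LIG A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CL2 LIG A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  N3  LIG A   1       2.000   0.000   0.000  1.00  0.00",
    "END"
  ))
  s <- read_structure(path)
  expect_equal(s$element, c("C", "CL", "N"))
})

test_that("duplicate atom labels are rejected", {
  path <- write_toy_pdb(c(
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  C1  LIG A   1       1.000   0.000   0.000  1.00  0.00           C",
    "END"
  ))
  expect_error(read_structure(path), "duplicate")
})

test_that("write -> read round trip preserves coordinates to PDB precision", {
  s <- make_structure(c("C1", "O1", "N1"), c("C", "O", "N"),
                      x = c(0.1234, -3.14159, 7), y = c(1, 2, 3),
                      z = c(-0.0005, 4.4444, 9.99999))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, path)
  back <- read_structure(path)
  expect_equal(back$x, s$x, tolerance = 1e-3)
  expect_equal(back$y, s$y, tolerance = 1e-3)
  expect_equal(back$z, s$z, tolerance = 1e-3)
  expect_equal(back$label, s$label)
})

test_that("charges join from a sidecar CSV", {
  path <- write_toy_pdb(c(
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  O1  LIG A   1       1.000   0.000   0.000  1.00  0.00           O",
    "END"
  ))
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(atom_label = c("C1", "O1"),
                                  charge_e = c(0.3, -0.3)), csv)
  s <- read_structure(path, charges_csv = csv)
  expect_equal(s$charge, c(0.3, -0.3))
})

test_that("two opposite charges 1 A apart give 1.000 Debye", {
  s <- make_structure(c("A", "B"), c("C", "C"), x = c(0, 1), y = c(0, 0),
                      z = c(0, 0), charge = c(0.2082, -0.2082))
  dm <- dipole_moment(s)
  # hand conversion oracle: q * d * 4.80321 D per e.A
  expect_equal(dm$magnitude, 0.2082 * 1 * 4.80321, tolerance = 1e-12)
  expect_equal(dm$magnitude, 1, tolerance = 1e-3)
  expect_equal(abs(dm$direction[1]), 1, tolerance = 1e-12)
})

test_that("dipole is invariant under rigid rotations and translations", {
  set.seed(30)
  s <- make_structure(paste0("A", 1:6), rep("C", 6),
                      x = rnorm(6), y = rnorm(6), z = rnorm(6),
                      charge = c(0.3, -0.1, -0.2, 0.25, -0.15, -0.1))
  ref <- dipole_moment(s)$magnitude
  for (i in 1:100) {
    r <- random_rotation()
    coords <- as.matrix(s[, c("x", "y", "z")]) %*% t(r)
    shift <- rnorm(3, sd = 10)
    s2 <- s
    s2$x <- coords[, 1] + shift[1]
    s2$y <- coords[, 2] + shift[2]
    s2$z <- coords[, 3] + shift[3]
    expect_equal(dipole_moment(s2)$magnitude, ref, tolerance = 1e-9)
  }
})

test_that("degenerate and invalid dipole inputs are handled", {
  s0 <- make_structure(c("A", "B"), c("C", "C"), x = c(0, 1), y = c(0, 0),
                       z = c(0, 0), charge = c(0, 0))
  dm <- dipole_moment(s0)
  expect_equal(dm$magnitude, 0)
  expect_false(dm$direction_defined)

  s_na <- make_structure(c("A", "B"), c("C", "C"), x = c(0, 1), y = c(0, 0),
                         z = c(0, 0), charge = c(0.1, NA))
  expect_error(dipole_moment(s_na), "B")

  s_net <- make_structure(c("A", "B"), c("C", "O"), x = c(0, 1), y = c(0, 0),
                          z = c(0, 0), charge = c(0.7, 0.3))
  expect_warning(dipole_moment(s_net), "origin-dependent")
})

test_that("published dipole magnitudes rank EPI > DOX > DAU > IDA", {
  d <- published_dipole_moments()
  expect_equal(names(sort(d, decreasing = TRUE)), c("EPI", "DOX", "DAU", "IDA"))
})

test_that("hydrogen-bond distances are exact and isometry-invariant", {
  s <- make_structure(c("H1", "O1", "C1"), c("H", "O", "C"),
                      x = c(0, 0, 5), y = c(0, 0, 5), z = c(0, 2.3, 5))
  expect_equal(hbond_distance(s, "H1", "O1"), 2.3)
  expect_error(hbond_distance(s, "H9", "O1"), "H9")

  set.seed(31)
  for (i in 1:20) {
    r <- random_rotation()
    coords <- as.matrix(s[, c("x", "y", "z")]) %*% t(r)
    shift <- rnorm(3, sd = 20)
    s2 <- s
    s2$x <- coords[, 1] + shift[1]
    s2$y <- coords[, 2] + shift[2]
    s2$z <- coords[, 3] + shift[3]
    expect_equal(hbond_distance(s2, "H1", "O1"), 2.3, tolerance = 1e-9)
  }
})
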