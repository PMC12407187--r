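test_that("structures round-trip through PDB files", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(TRI, f)
  s2 <- read_structure(f)
  expect_identical(chain_ids(s2), chain_ids(TRI))
  expect_identical(nrow(s2), nrow(TRI))
  expect_lt(max(abs(ca_coords(s2) - ca_coords(TRI))), 1e-3)
  expect_identical(s2$role, TRI$role)
  expect_identical(chain_sequence(s2, "B"), chain_sequence(TRI, "B"))
  expect_identical(helix_ranges(s2, "C"), helix_ranges(TRI, "C"))

  # 30-chain assembly writes and re-reads
  f2 <- withr::local_tempfile(fileext = ".pdb")
  asm_small <- realize_dock(SMALL_CROWN, SMALL_CROWN,
                            list(phi = 0, z_offset = 200, truncation = 0))
  write_structure(asm_small, f2)
  expect_length(chain_ids(read_structure(f2)), 30)
})

test_that("constructed two-chain fixture reads with expected counts", {
  lines <- c(
    sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:20, rep(c("A", "B"), each = 10), rep(1:10, 2),
            seq(0, 19) * 3.8, rep(0, 20), rep(c(0, 5), each = 10)),
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f)
  expect_length(chain_ids(s), 2)
  expect_equal(unname(table(s$chain)), c(10L, 10L), ignore_attr = TRUE)
})

test_that("reading rejects residues without CA and bad files", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  N   ALA A   2       3.800   0.000   0.000  1.00  0.00           N",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(read_structure(f), "without CA")
  expect_error(read_structure(withr::local_tempfile()), "not found")
})

test_that("writing enforces structure invariants", {
  expect_error(write_structure(TRI[0, ], withr::local_tempfile()), "empty")
  dup <- dplyr::bind_rows(TRI, get_chain(TRI, "A"))
  class(dup) <- class(TRI)
  expect_error(write_structure(dup, withr::local_tempfile()), "duplicate")
  expect_error(write_structure(TRI, withr::local_tempfile(), format = "mmcif"),
               "not supported")
})

test_that("rigid transforms obey group laws", {
  withr::local_seed(42)
  for (i in 1:25) {
    t1 <- random_transform()
    t2 <- random_transform()
    t3 <- random_transform()
    # inverse composes to identity
    id <- transform_compose(t1, transform_inverse(t1))
    expect_lt(max(abs(id$rotation - diag(3))), 1e-8)
    expect_lt(max(abs(id$translation)), 1e-8)
    # associativity
    a <- transform_compose(transform_compose(t1, t2), t3)
    b <- transform_compose(t1, transform_compose(t2, t3))
    expect_lt(max(abs(a$rotation - b$rotation)), 1e-8)
    expect_lt(max(abs(a$translation - b$translation)), 1e-8)
  }
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
})

test_that("apply_transform is an isometry and handles simple cases", {
  expect_equal(apply_transform(TRI, transform_identity()), TRI)
  shifted <- apply_transform(TRI, translation(c(0, 0, 10)))
  expect_equal(shifted$z, TRI$z + 10)
  expect_equal(shifted$x, TRI$x)

  withr::local_seed(7)
  pts <- matrix(rnorm(9, sd = 5), 3, 3)
  d_before <- as.numeric(dist(pts))
  for (i in 1:10) {
    moved <- apply_transform(pts, random_transform())
    expect_lt(max(abs(as.numeric(dist(moved)) - d_before)), 1e-8)
  }
  # whole-structure pairwise distances preserved
  ca <- ca_coords(get_chain(TRI, "A"))
  moved <- apply_transform(ca, random_transform())
  expect_lt(max(abs(as.numeric(dist(moved)) - as.numeric(dist(ca)))), 1e-8)
})

test_that("superpose recovers exact transforms and degenerate errors", {
  withr::local_seed(3)
  m <- matrix(rnorm(30, sd = 4), 10, 3)
  res <- superpose(m, m)
  expect_lt(res$rmsd, 1e-10)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-6)

  rot <- apply_transform(m, rot_z(72))
  res72 <- superpose(m, rot)
  expect_lt(res72$rmsd, 1e-8)
  expect_lt(abs(rotation_angle_about_axis(res72$transform, c(0, 0, 1)) - 72),
            1e-6)

  expect_error(superpose(m[1:2, ], m[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("superpose is idempotent and matches an independent reference", {
  withr::local_seed(4)
  m <- matrix(rnorm(45, sd = 6), 15, 3)
  target <- apply_transform(m, random_transform()) + matrix(rnorm(45, sd = 0.3), 15, 3)
  r1 <- superpose(m, target)
  moved <- apply_transform(m, r1$transform)
  r2 <- superpose(moved, target)
  expect_lt(abs(r1$rmsd - r2$rmsd), 1e-10)
  # independent reference: bio3d's least-squares fit
  ref <- bio3d::fit.xyz(as.numeric(t(target)), as.numeric(t(m)),
                        fixed.inds = 1:45, mobile.inds = 1:45)
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - target)^2)))
  expect_lt(abs(r1$rmsd - ref_rmsd), 1e-6)
})

test_that("planar superposition agrees with a brute-force rotation grid", {
  # 4 points in the z = 0 plane, known in-plane transform plus known
  # per-point displacements: the optimal rotation is about z, so an
  # exhaustive 1-D angle scan is a valid independent minimizer
  pts <- cbind(c(0, 4, 4, 0), c(0, 0, 3, 3), 0)
  disp <- cbind(c(0.2, -0.1, 0.15, -0.2), c(-0.1, 0.2, 0.1, -0.15), 0)
  target <- apply_transform(pts, transform_compose(translation(c(2, -1, 0)),
                                                   rot_z(33))) + disp
  fit <- superpose(pts, target)
  grid_rmsd <- function(ang) {
    rot <- apply_transform(pts, rot_z(ang))
    shift <- colMeans(target) - colMeans(rot)
    sqrt(mean(rowSums((sweep(rot, 2, -shift) - target)^2)))
  }
  brute <- min(vapply(seq(0, 359.99, by = 0.02), grid_rmsd, numeric(1)))
  expect_lt(abs(fit$rmsd - brute), 1e-3)
})

test_that("rotation angle extraction is exact and validates the axis", {
  expect_equal(rotation_angle_about_axis(transform_identity(), c(0, 0, 1)), 0)
  expect_lt(abs(rotation_angle_about_axis(rot_z(25), c(0, 0, 1)) - 25), 1e-9)
  two <- transform_compose(rot_z(72), rot_z(72))
  expect_lt(abs(rotation_angle_about_axis(two, c(0, 0, 1)) - 144), 1e-9)
  expect_error(rotation_angle_about_axis(rot_x(30), c(0, 0, 1)),
               "not parallel")
  expect_error(rotation_angle_about_axis(rot_z(30), c(0, 0, 2)), "unit")
})
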