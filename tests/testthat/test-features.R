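test_that("signed dihedral follows the cis = 0 convention on planar and out-of-plane quadruples", {
  # planar cis and trans
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), pi)
  # out-of-plane: +pi/2 under the stated convention
  expect_equal(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)),
               pi / 2)
  # agreement with two independent oracles on random quadruples
  set.seed(42)
  for (i in 1:25) {
    q <- matrix(rnorm(12), 4, 3)
    ref <- oracle_dihedral(q[1, ], q[2, ], q[3, ], q[4, ])
    got <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
    expect_equal(got, ref, tolerance = 1e-12)
    b3d <- bio3d::torsion.xyz(as.vector(t(q)), atm.inc = 4) * pi / 180
    expect_equal(got, as.numeric(b3d), tolerance = 1e-6)
  }
})

test_that("dihedral values are invariant under rigid motion of the quadruple", {
  set.seed(7)
  q <- matrix(rnorm(12), 4, 3)
  ref <- dihedral_angle(q[1, ], q[2, ], q[3, ], q[4, ])
  for (s in 1:10) {
    qr_ <- random_rigid(q, seed = s)
    expect_equal(dihedral_angle(qr_[1, ], qr_[2, ], qr_[3, ], qr_[4, ]), ref,
                 tolerance = 1e-10)
  }
})

test_that("compute_dihedrals recovers known torsions and rejects undefined angles", {
  set.seed(3)
  ang <- runif(40, -3.1, 3.1)
  traj <- toy_dihedral_traj(ang)
  d <- compute_dihedrals(traj, dihedral_selection(41, "chi1"))
  expect_equal(drop(d$values), ang, tolerance = 1e-12)
  expect_equal(colnames(d$values), "chi1_TRP41")
  expect_equal(unname(d$atoms["chi1_TRP41", ]), 1:4)
  # ALA has no chi2; missing residues and kinds error loudly
  traj$atoms$resid <- "ALA"
  expect_error(compute_dihedrals(traj, dihedral_selection(41, "chi2")),
               "no chi2")
  expect_error(compute_dihedrals(traj, dihedral_selection(99, "chi1")),
               "not found")
  expect_error(compute_dihedrals(traj, dihedral_selection(41, "omega")),
               "unknown angle kind")
})

test_that("sincos_expand interleaves features, preserves segments and is invertible", {
  set.seed(11)
  v <- matrix(runif(60, -pi, pi), 20, 3)
  d <- dihedral_series(v, labels = c("chi1_TRP41", "chi2_TRP41", "phi_GLY7"),
                       segments = c(1L, 11L))
  fs <- sincos_expand(d)
  expect_equal(ncol(fs$values), 6L)
  expect_equal(colnames(fs$values),
               c("sin_chi1_TRP41", "cos_chi1_TRP41", "sin_chi2_TRP41",
                 "cos_chi2_TRP41", "sin_phi_GLY7", "cos_phi_GLY7"))
  expect_equal(fs$segments, d$segments)
  # sin^2 + cos^2 = 1 and atan2 reconstruction per angle
  for (j in 1:3) {
    s <- fs$values[, 2 * j - 1]; co <- fs$values[, 2 * j]
    expect_lt(max(abs(s^2 + co^2 - 1)), 1e-12)
    expect_lt(max(abs(atan2(s, co) - v[, j])), 1e-12)
  }
  # angle 0 -> (0, 1)
  d0 <- dihedral_series(matrix(0, 2, 1), labels = "chi1_TRP41")
  expect_equal(unname(sincos_expand(d0)$values[1, ]), c(0, 1))
})

test_that("concat_segments stacks rows, records trajectory starts, and is associative", {
  mk <- function(n, seed) {
    set.seed(seed)
    feature_series(matrix(rnorm(n * 2), n, 2), names = c("a", "b"))
  }
  s1 <- mk(5, 1); s2 <- mk(7, 2); s3 <- mk(4, 3)
  cc <- concat_segments(s1, s2)
  expect_equal(nrow(cc$values), 12L)
  expect_equal(cc$segments, c(1L, 6L))
  # single input is the identity
  expect_equal(concat_segments(s1)$values, s1$values)
  # associativity of the observable output
  left <- concat_segments(concat_segments(s1, s2), s3)
  right <- concat_segments(s1, concat_segments(s2, s3))
  expect_equal(left$values, right$values)
  expect_equal(left$segments, right$segments)
  # per-segment means recomputed from the concatenation match the originals
  all3 <- concat_segments(s1, s2, s3)
  bounds <- c(all3$segments, nrow(all3$values) + 1L)
  for (i in 1:3) {
    rows <- bounds[i]:(bounds[i + 1] - 1L)
    expect_equal(colMeans(all3$values[rows, , drop = FALSE]),
                 colMeans(list(s1, s2, s3)[[i]]$values))
  }
  # mismatches are rejected
  s_bad <- feature_series(matrix(rnorm(10), 5, 2), names = c("a", "c"))
  expect_error(concat_segments(s1, s_bad), "names differ")
  s_dt <- feature_series(matrix(rnorm(10), 5, 2), names = c("a", "b"),
                         dt_ps = 2)
  expect_error(concat_segments(s1, s_dt), "spacing differs")
})

test_that("trajectory writers round-trip through the readers", {
  set.seed(5)
  ang <- runif(30, -3, 3)
  traj <- toy_dihedral_traj(ang)
  top <- tempfile(fileext = ".pdb")
  write_pdb_traj(traj, top, frames = 1)
  # DCD: single precision, well inside 1e-6 nm
  dcd <- tempfile(fileext = ".dcd")
  write_dcd(traj$xyz, dcd)
  rt <- read_trajectory(dcd, top)
  expect_equal(nrow(rt$xyz), 30L)
  expect_lt(max(abs(rt$xyz - traj$xyz)), 1e-6)
  expect_equal(rt$atoms$resid[1], "TRP")
  # multi-model PDB as its own topology (format precision 1e-4 nm)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_traj(traj, pdb)
  rt2 <- read_trajectory(pdb)
  expect_equal(nrow(rt2$xyz), 30L)
  expect_lt(max(abs(rt2$xyz - traj$xyz)), 1e-4)
  # atom-count mismatch between topology and trajectory
  bigger <- coord_traj(cbind(traj$xyz, traj$xyz[, 1:3]),
                       rbind(traj$atoms,
                             data.frame(elety = "CD1", resid = "TRP",
                                        resno = 41L, chain = "A")))
  top5 <- tempfile(fileext = ".pdb")
  write_pdb_traj(bigger, top5, frames = 1)
  expect_error(read_trajectory(dcd, top5), "mismatch")
  expect_error(read_trajectory(tempfile(fileext = ".dcd"), top), "not found")
})

test_that("feature series TSV round trip preserves values, names, segments, spacing", {
  set.seed(9)
  fs <- feature_series(matrix(rnorm(40), 20, 2), names = c("sin_a", "cos_a"),
                       segments = c(1L, 9L), dt_ps = 2.5)
  f <- tempfile(fileext = ".tsv")
  write_feature_series(fs, f)
  back <- read_feature_series(f)
  expect_identical(back$values, fs$values)
  expect_identical(back$segments, fs$segments)
  expect_identical(back$dt_ps, fs$dt_ps)
  bad <- tempfile()
  writeLines(c("time x", "0 1"), bad)
  expect_error(read_feature_series(bad), "not a slowcv feature_series")
  # torsion atom tables survive the round trip
  d <- two_state_dihedral(n = 50, n_fast = 1, seed = 4)
  fst <- sincos_expand(d)
  write_feature_series(fst, f)
  expect_identical(attr(read_feature_series(f), "torsion_atoms"),
                   attr(fst, "torsion_atoms"))
})

test_that("container invariants are enforced", {
  expect_error(feature_series(matrix(1:6, 3, 2), names = c("a", "a")),
               "unique")
  expect_error(feature_series(matrix(c(1, NA, 3, 4), 2, 2),
                              names = c("a", "b")), "missing")
  expect_error(feature_series(matrix(1:8, 4, 2), names = c("a", "b"),
                              segments = c(1L, 4L)), "at least 2")
  expect_error(feature_series(matrix(1:8, 4, 2), names = c("a", "b"),
                              segments = c(2L, 3L)), "begin at 1")
  expect_error(dihedral_series(matrix(7, 2, 1), labels = "x"),
               "-pi, pi")
})
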