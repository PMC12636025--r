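test_that("distance series: 3-4-5 triangle, constant program, histogram conservation", {
  coords <- array(0, c(1, 2, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  traj <- md_trajectory(coords)
  ds <- distance_series(traj, 1, 2)
  expect_equal(ds$values, 5)

  gen <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 200, distance_program = 3.5, seed = 1))
  ds2 <- distance_series(gen$traj, "OG", "C1")
  expect_true(all(abs(ds2$values - 3.5) < 1e-12))
  expect_equal(sum(ds2$counts), 200)          # counts conserve frame count
  expect_equal(sum(ds2$counts > 0), 1)        # single occupied bin

  # seeded noisy program: histogram mode falls in the programmed mean bin
  noisy <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 5000, distance_program = 3.5, noise_sigma = 0.2, seed = 2))
  ds3 <- distance_series(noisy$traj, "OG", "C1")
  expect_lt(abs(ds3$mode - 3.5), 0.15)
  expect_equal(sum(ds3$counts), 5000)
})

test_that("dihedral series: cis 0, trans 180, rotation invariance, degenerate NA", {
  cis <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  trans <- rbind(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0))
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  traj <- md_trajectory(list(cis, trans, lin))
  dh <- dihedral_series(traj, 1:4)
  expect_equal(dh$values[1], 0)
  expect_equal(dh$values[2], 180)     # wrapped to (-180, 180]
  expect_true(is.na(dh$values[3]))

  # randomly rotated + translated copies give identical dihedrals
  set.seed(21)
  base <- matrix(rnorm(12), 4)
  ref <- dihedral_series(md_trajectory(list(base)), 1:4)$values
  for (i in 1:10) {
    moved <- sweep(base %*% t(random_rotation()), 2, rnorm(3), `+`)
    got <- dihedral_series(md_trajectory(list(moved)), 1:4)$values
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD: identity, rigid motions, and never exceeding raw RMSD", {
  set.seed(22)
  x <- matrix(rnorm(30), 10)
  expect_equal(rmsd(x, x), 0)

  # randomly rotated + translated copy superposes to ~0
  moved <- sweep(x %*% t(random_rotation()), 2, c(5, -3, 2), `+`)
  expect_lt(rmsd(x, moved, superpose = TRUE), 1e-8)

  # 3-point set under a 1 A rigid shift: raw 1 A, superposed 0
  tri <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2, 0))
  shifted <- sweep(tri, 2, c(1, 0, 0), `+`)
  expect_equal(rmsd(tri, shifted, superpose = FALSE), 1)
  expect_lt(rmsd(tri, shifted, superpose = TRUE), 1e-10)

  # Kabsch result never exceeds raw RMSD
  for (i in 1:20) {
    a <- matrix(rnorm(24), 8)
    b <- a + matrix(rnorm(24, sd = 0.5), 8)
    expect_lte(rmsd(a, b, superpose = TRUE),
               rmsd(a, b, superpose = FALSE) + 1e-12)
  }

  expect_error(rmsd(x, x, selection = integer(0)), "empty selection")
})

test_that("Kabsch RMSD agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(23)
  for (i in 1:10) {
    a <- matrix(rnorm(45), 15)
    b <- a + matrix(rnorm(45, sd = 0.8), 15)
    ours <- rmsd(a, b, superpose = TRUE)
    theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    # bio3d reports RMSD rounded to 3 decimals
    expect_equal(ours, theirs, tolerance = 1e-3)
  }
})

test_that("per-residue RMSD isolates a displaced residue after a global fit", {
  set.seed(24)
  n <- 12
  coords <- matrix(rnorm(3 * n, sd = 3), n)
  atoms <- data.frame(name = paste0("A", 1:n), element = "C",
                      resid = rep(1:4, each = 3), resname = "RES")
  traj <- md_trajectory(array(rep(coords, each = 2), c(2, n, 3)),
                        atoms = atoms)

  # identical structures: all zeros
  pr0 <- per_residue_rmsd(traj, 1, 2)
  expect_true(all(pr0$rmsd < 1e-10))

  # displace residue 3 rigidly by 4 A, fit on the rest
  moved <- coords
  moved[atoms$resid == 3, 1] <- moved[atoms$resid == 3, 1] + 4
  fit_sel <- which(atoms$resid != 3)
  pr <- per_residue_rmsd(traj, coords, moved, fit_selection = fit_sel)
  expect_equal(pr$rmsd[pr$resid == 3], 4, tolerance = 0.01)
  expect_true(all(pr$rmsd[pr$resid != 3] < 0.01))

  # whole-structure rigid motion: all ~0 after fitting
  rigid <- sweep(coords %*% t(random_rotation()), 2, c(1, 2, 3), `+`)
  pr2 <- per_residue_rmsd(traj, coords, rigid)
  expect_true(all(pr2$rmsd < 1e-8))
})

test_that("water occupancy counts site waters and flags identity exchanges", {
  near <- function(i) c(0.3 * i, 0.2, 0.1)
  # 4 waters (resids 11:14) stay in the site for 5 frames
  frames <- replicate(5, setNames(lapply(1:4, near), 11:14),
                      simplify = FALSE)
  traj <- site_water_trajectory(frames)
  occ <- water_occupancy(traj, select_atoms(traj, name = c("OG", "C1")),
                         cutoff = 5)
  expect_equal(occ$counts, rep(4L, 5))
  expect_length(occ$exchange_events, 0)

  # swap water 14 for water 15 at frame 4: constant count, one exchange
  frames2 <- frames
  for (f in 4:5) {
    frames2[[f]] <- setNames(lapply(1:4, near), c(11, 12, 13, 15))
  }
  traj2 <- site_water_trajectory(frames2)
  occ2 <- water_occupancy(traj2, select_atoms(traj2, name = c("OG", "C1")),
                          cutoff = 5)
  expect_equal(occ2$counts, rep(4L, 5))
  expect_equal(occ2$exchange_events, 4L)

  # cutoff 0: all counts 0
  occ0 <- water_occupancy(traj, select_atoms(traj, name = "OG"), cutoff = 0)
  expect_equal(occ0$counts, rep(0L, 5))

  # roster without waters warns and returns zeros
  dry <- md_trajectory(array(0, c(2, 2, 3)))
  expect_warning(occd <- water_occupancy(dry, 1, cutoff = 5), "no water")
  expect_equal(occd$counts, c(0L, 0L))
})

test_that("unbinding detection honors threshold and persistence", {
  gen <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 1000, distance_program = 3.5, unbind_frame = 400, seed = 6))
  ds <- distance_series(gen$traj, "OG", "C1")
  expect_equal(detect_unbinding(ds, threshold = 10, persistence = 50), 400L)

  # never above threshold
  expect_true(is.na(detect_unbinding(rep(3, 100), 10, 5)))

  # a short spike does not trigger
  v <- rep(3, 100); v[40:42] <- 20
  expect_true(is.na(detect_unbinding(v, 10, persistence = 5)))
  expect_equal(detect_unbinding(v, 10, persistence = 3), 40L)
})

test_that("geometric observables are invariant under global rigid motion of all frames", {
  gen <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 50, n_atoms = 6, distance_program = c(3, 5), seed = 7))
  traj <- gen$traj
  rot <- random_rotation(); shift <- c(4, -2, 9)
  moved <- traj$coords
  for (f in 1:traj$n_frames) {
    moved[f, , ] <- sweep(matrix(traj$coords[f, , ], ncol = 3) %*% t(rot),
                          2, shift, `+`)
  }
  traj2 <- md_trajectory(moved, atoms = traj$atoms)
  expect_equal(distance_series(traj2, "OG", "C1")$values,
               distance_series(traj, "OG", "C1")$values, tolerance = 1e-10)
  expect_equal(dihedral_series(traj2, c(1, 2, 3, 4))$values,
               dihedral_series(traj, c(1, 2, 3, 4))$values,
               tolerance = 1e-6)
  expect_lt(rmsd(matrix(traj$coords[1, , ], ncol = 3),
                 matrix(moved[1, , ], ncol = 3), superpose = TRUE), 1e-8)
})

test_that("selection helpers and atom resolution behave", {
  gen <- generate_trajectory(synthetic_trajectory_spec(n_atoms = 6,
                                                       n_frames = 3,
                                                       seed = 8))
  traj <- gen$traj
  expect_equal(select_atoms(traj, resname = "LIG"), 2L)
  expect_equal(select_atoms(traj, element = "O"), 1L)
  expect_error(distance_series(traj, "NOPE", "C1"), "unknown")
  expect_error(dihedral_series(traj, c(1, 1, 2, 3)), "distinct")
})

test_that("multi-model PDB and XYZ trajectory round trips preserve analysis results", {
  gen <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 4, n_atoms = 5, distance_program = c(3, 8), seed = 9))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_trajectory(gen$traj, f)
  back <- read_pdb_trajectory(f)
  expect_equal(back$n_frames, 4)
  expect_equal(back$atoms$resname, gen$traj$atoms$resname)
  expect_equal(distance_series(back, "OG", "C1")$values,
               distance_series(gen$traj, "OG", "C1")$values,
               tolerance = 1e-3)

  fx <- withr::local_tempfile(fileext = ".xyz")
  frames <- lapply(1:4, function(i) matrix(gen$traj$coords[i, , ], ncol = 3))
  write_xyz(gen$traj$atoms$element, frames, fx)
  tx <- read_xyz_trajectory(fx)
  expect_equal(tx$n_frames, 4)
  expect_equal(distance_series(tx, 1, 2)$values,
               distance_series(gen$traj, 1, 2)$values, tolerance = 1e-6)
})
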