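test_that("seeded generation is reproducible bit for bit", {
  spec <- synthetic_fep_spec(seed = 99, n_windows = 5,
                             n_samples_per_window = 100)
  expect_identical(generate_fep_windows(spec), generate_fep_windows(spec))

  tspec <- synthetic_titration_spec(seed = 99)
  expect_identical(generate_titration(tspec), generate_titration(tspec))

  pspec <- synthetic_progress_spec(seed = 99)
  expect_identical(generate_progress(pspec), generate_progress(pspec))

  jspec <- synthetic_trajectory_spec(seed = 99, n_frames = 20)
  expect_identical(generate_trajectory(jspec), generate_trajectory(jspec))

  # different seeds diverge
  expect_false(identical(
    generate_fep_windows(synthetic_fep_spec(seed = 1, n_windows = 5,
                                            n_samples_per_window = 50)),
    generate_fep_windows(synthetic_fep_spec(seed = 2, n_windows = 5,
                                            n_samples_per_window = 50))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(generate_fep_windows(synthetic_fep_spec(seed = 5,
                                                    n_windows = 3,
                                                    n_samples_per_window = 10)))
  expect_identical(rnorm(1), a)
})

test_that("zero-noise FEP windows pass through the estimator exactly", {
  # all truth on the gas-phase term
  spec <- synthetic_fep_spec(noise_sigma = 0, qm_fraction = 1,
                             n_samples_per_window = 5, seed = 1)
  gen <- generate_fep_windows(spec)
  prof <- suppressWarnings(fep_profile(gen$windows))
  expect_equal(prof$dG, gen$truth$G)
  expect_equal(prof$stderr, rep(0, spec$n_windows))

  # all truth on the interaction term
  spec2 <- synthetic_fep_spec(noise_sigma = 0, qm_fraction = 0,
                              n_samples_per_window = 5, seed = 1)
  gen2 <- generate_fep_windows(spec2)
  prof2 <- suppressWarnings(fep_profile(gen2$windows))
  expect_equal(prof2$dG, gen2$truth$G, tolerance = 1e-10)
})

test_that("noisy double-well windows are recovered within 3 propagated errors", {
  spec <- synthetic_fep_spec(noise_sigma = 0.5, n_samples_per_window = 2000,
                             n_windows = 21,
                             truth = truth_profile("double_well",
                                                   barrier = 10),
                             seed = 31)
  gen <- generate_fep_windows(spec)
  prof <- fep_profile(gen$windows, temperature = 303)
  dev <- abs(prof$dG - gen$truth$G)[-1]
  expect_true(all(dev < 3 * prof$stderr[-1]))
})

test_that("AR(1) windows keep the stationary spread and raise the error estimate", {
  spec <- synthetic_fep_spec(ar1 = 0.9, noise_sigma = 0.5,
                             n_samples_per_window = 5000, n_windows = 2,
                             seed = 17)
  gen <- generate_fep_windows(spec)
  x <- gen$windows[[1]]$samples
  expect_equal(sd(x), 0.5, tolerance = 0.1)
  expect_equal(cor(x[-1], x[-length(x)]), 0.9, tolerance = 0.05)
})

test_that("titration generator follows the Hill law at the midpoint and in the tails", {
  spec <- synthetic_titration_spec(pka_true = 9, hill_true = 1.5,
                                   ph_grid = seq(5, 13, 0.5),
                                   n_samples_per_ph = 4000, seed = 41)
  gen <- generate_titration(spec)
  i_mid <- which(spec$ph_grid == 9)
  expect_equal(gen$series$fraction[i_mid], 0.5, tolerance = 0.05)
  expect_gt(gen$series$fraction[1], 0.99)
  expect_lt(gen$series$fraction[length(spec$ph_grid)], 0.01)
  expect_equal(gen$truth$fraction,
               1 / (1 + 10^(1.5 * (spec$ph_grid - 9))))
})

test_that("progress generator limits: linear at k_inact = 0, plateau v0/k_inact", {
  lin <- generate_progress(synthetic_progress_spec(v0 = 2, k_inact = 0,
                                                   noise_sigma = 0,
                                                   seed = 1))
  expect_equal(lin$curve$concentrations, 2 * lin$curve$times)

  sat <- generate_progress(synthetic_progress_spec(v0 = 4, k_inact = 0.5,
                                                   noise_sigma = 0,
                                                   t_grid = c(0, 1, 2, 5,
                                                              10, 50, 100),
                                                   seed = 1))
  expect_equal(sat$truth$plateau, 8)
  expect_equal(sat$curve$concentrations[7], 8, tolerance = 1e-6)
})

test_that("trajectory generator realizes the distance program and the unbinding bound", {
  gen <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 100, distance_program = 3.5, seed = 3))
  d <- distance_series(gen$traj, "OG", "C1")$values
  expect_true(all(abs(d - 3.5) < 1e-12))

  gen2 <- generate_trajectory(synthetic_trajectory_spec(
    n_frames = 1000, unbind_frame = 400, seed = 3))
  d2 <- distance_series(gen2$traj, "OG", "C1")$values
  expect_true(all(d2[400:1000] >= 15))
  expect_true(all(d2[1:399] < 10))
  expect_equal(gen2$truth$unbind_frame, 400L)

  # identity frames give an all-zero RMSD series
  traj <- gen$traj
  r <- vapply(seq_len(traj$n_frames), function(f) {
    rmsd(matrix(traj$coords[1, , ], ncol = 3),
         matrix(traj$coords[f, , ], ncol = 3), superpose = FALSE)
  }, numeric(1))
  expect_true(all(r < 1e-12))
})

test_that("spec validation names the offending field", {
  expect_error(synthetic_fep_spec(n_windows = 1), "n_windows")
  expect_error(synthetic_fep_spec(noise_sigma = -1), "noise_sigma")
  expect_error(synthetic_fep_spec(qm_fraction = 1.2), "qm_fraction")
  expect_error(synthetic_fep_spec(n_samples_per_window = 0),
               "n_samples_per_window")
  expect_error(synthetic_titration_spec(ph_grid = c(7, 7)), "ph_grid")
  expect_error(synthetic_progress_spec(v0 = -1), "v0")
  expect_error(synthetic_progress_spec(t_grid = c(2, 1)), "t_grid")
  expect_error(synthetic_trajectory_spec(unbind_frame = 50, n_frames = 10),
               "unbind_frame")
})

test_that("truth records serialize to JSON", {
  gen <- generate_titration(synthetic_titration_spec(seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_truth_record(gen$truth, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$pka, 10.5)
})
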