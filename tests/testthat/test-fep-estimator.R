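kT303 <- fepland::phys_constants$R_kcal * 303

test_that("interaction terms vanish when all windows share a constant interaction energy", {
  windows <- lapply(1:5, function(i) {
    fep_window(i, (i - 1) / 4, e_qm0 = i^2, samples = rep(7.3, 50))
  })
  prof <- fep_profile(windows, temperature = 303)
  expect_equal(prof$dG, (1:5)^2 - 1)
  expect_equal(prof$stderr, rep(0, 5))
})

test_that("two-sample paired increment matches the hand-computed log-mean-exp", {
  de <- c(0, kT303 * log(4))
  expect_equal(zwanzig_increment(de, 303), -kT303 * log((1 + 0.25) / 2))
  # as_printed flips the sign inside the exponential
  expect_equal(zwanzig_increment(de, 303, "as_printed"),
               -kT303 * log((1 + 4) / 2))
})

test_that("Gaussian samples reproduce the closed form mu - sigma^2/(2 kB T)", {
  mu <- 1.2; sigma <- 0.6; n <- 1e5
  set.seed(42)
  de <- rnorm(n, mu, sigma)
  g <- zwanzig_increment(de, 303)
  se <- window_error(de, 303)
  expect_lt(abs(g - (mu - sigma^2 / (2 * kT303))), 3 * se)
})

test_that("zwanzig and as_printed agree at zero dE and differ otherwise", {
  expect_equal(zwanzig_increment(rep(0, 10), 303),
               zwanzig_increment(rep(0, 10), 303, "as_printed"))
  de <- c(-0.5, 0.2, 0.9, 1.4)
  expect_false(isTRUE(all.equal(zwanzig_increment(de, 303),
                                zwanzig_increment(de, 303, "as_printed"))))
})

test_that("log-sum-exp evaluation survives |dE| up to 1e4 kcal/mol", {
  expect_true(is.finite(zwanzig_increment(c(-1e4, -9999, -9998), 303)))
  expect_true(is.finite(zwanzig_increment(c(1e4, 9999), 303)))
  expect_equal(zwanzig_increment(rep(-1e4, 5), 303), -1e4)
})

test_that("window error is 0 at zero variance, scales as 1/sqrt(n), grows with autocorrelation", {
  expect_equal(window_error(rep(2, 100), 303), 0)

  set.seed(7)
  n <- 2000
  errs <- replicate(30, c(window_error(rnorm(n, 0, 0.5), 303),
                          window_error(rnorm(4 * n, 0, 0.5), 303)))
  # ratio of mean errors over replicates (individual ratios are noisy with
  # only 10 blocks behind each estimate)
  expect_equal(mean(errs[1, ]) / mean(errs[2, ]), 2, tolerance = 0.15)

  # AR(1) rho = 0.9: block-averaged error above the naive i.i.d. error
  set.seed(8)
  n <- 5000
  x <- numeric(n)
  x[1] <- rnorm(1)
  for (i in 2:n) x[i] <- 0.9 * x[i - 1] + sqrt(1 - 0.81) * rnorm(1)
  x <- 0.5 * x
  blocked <- window_error(x, 303, blocks = 10)
  naive <- window_error(x, 303, blocks = n %/% 2)  # blocks of 2 ~ naive
  expect_gt(blocked, naive)

  expect_error(window_error(1, 303), "at least 2")
  expect_warning(window_error(rnorm(10), 303), "fewer than 20")
})

test_that("profile error propagation is a quadrature sum", {
  expect_equal(propagate_profile_error(3), c(0, 3))
  expect_equal(propagate_profile_error(c(3, 4)), c(0, 3, 5))
  set.seed(5)
  for (i in 1:10) {
    e <- runif(8)
    brute <- c(0, sapply(1:8, function(j) sqrt(sum(e[1:j]^2))))
    expect_equal(propagate_profile_error(e), brute)
  }
  expect_error(propagate_profile_error(c(1, -1)), "nonnegative")
})

test_that("profile is invariant under common shifts of E_qm0 and of interaction samples", {
  gen <- generate_fep_windows(synthetic_fep_spec(n_windows = 6, seed = 3,
                                                 n_samples_per_window = 400))
  base <- fep_profile(gen$windows)
  shifted <- lapply(gen$windows, function(w) {
    fep_window(w$index, w$s, w$e_qm0 + 123.4, w$samples - 55.5)
  })
  prof2 <- fep_profile(shifted)
  expect_equal(prof2$dG, base$dG, tolerance = 1e-9)
  expect_equal(prof2$stderr, base$stderr, tolerance = 1e-9)
})

test_that("noisy synthetic profiles are recovered within propagated errors", {
  # stochastic recovery across seeded replicates (scaled-down version of the
  # full acceptance check)
  hits <- integer(0)
  for (seed in 1:20) {
    gen <- generate_fep_windows(synthetic_fep_spec(seed = seed))
    prof <- fep_profile(gen$windows, temperature = 303)
    dev <- abs(prof$dG - gen$truth$G)[-1]
    hits <- c(hits, dev < 3 * prof$stderr[-1])
  }
  expect_gte(mean(hits), 0.95)
})

test_that("single window and empty samples are handled", {
  w <- fep_window(1, 0, 5, rnorm(10))
  prof <- fep_profile(list(w))
  expect_equal(prof$dG, 0)
  expect_error(fep_window(1, 0, 5, numeric(0)), "samples")
})

test_that("stationary-point corrections shift barriers by vibrational differences", {
  prof <- data.frame(s = 0:4, dG = c(0, 3, 10, 6, 2))
  labels <- c("R", NA, "TS", NA, "P")

  # equal corrections leave every gap unchanged
  eq <- apply_stationary_corrections(prof, c(R = 2, TS = 2, P = 2), labels)
  expect_equal(eq$dG_corrected, prof$dG[c(1, 3, 5)])

  # reference 0, TS -1.2 lowers the barrier by 1.2
  co <- apply_stationary_corrections(prof, c(R = 0, TS = -1.2, P = 0.3),
                                     labels)
  expect_equal(co$dG_corrected[2] - co$dG_corrected[1], 10 - 1.2)

  # corrections from harmonic analysis equal the hand-computed ZPE shift
  wf <- phys_constants$wavenumber_factor
  h_r <- hessian_block(matrix((1000 / wf)^2, 1, 1), 1)
  h_ts <- hessian_block(matrix((800 / wf)^2, 1, 1), 1)
  zr <- zpe(normal_modes(h_r))
  zt <- zpe(normal_modes(h_ts))
  co2 <- apply_stationary_corrections(prof, c(R = zr, TS = zt, P = zr),
                                      labels)
  expect_equal(co2$correction[2], (800 - 1000) / 2 *
                 phys_constants$kcal_per_wavenumber)

  expect_error(apply_stationary_corrections(prof, c(R = 0), labels),
               "unknown label")
})

test_that("window TSV and profile CSV round trip", {
  gen <- generate_fep_windows(synthetic_fep_spec(n_windows = 4, seed = 2,
                                                 n_samples_per_window = 25))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_fep_windows(gen$windows, f, comment = "synthetic demo")
  back <- read_fep_windows(f)
  expect_equal(length(back), 4)
  expect_equal(back[[3]]$samples, gen$windows[[3]]$samples)
  expect_equal(back[[3]]$e_qm0, gen$windows[[3]]$e_qm0)

  prof <- fep_profile(gen$windows)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_profile(prof, fp)
  d <- read.csv(fp)
  expect_equal(d$dG, prof$dG)
})
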