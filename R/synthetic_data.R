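#' Truth profiles for synthetic FEP data
#'
#' Built-in ground-truth free-energy profiles over a path coordinate
#' normalized to `[0, 1]`:
#' \describe{
#'   \item{double_well}{`G(s) = barrier * sin(pi s)^2 + dg * s^2 (3 - 2 s)`
#'     — minima at both ends separated by a barrier, with overall reaction
#'     free energy `dg`.}
#'   \item{piecewise}{linear interpolation through supplied `knots_s`,
#'     `knots_g`.}
#' }
#'
#' @param label `"double_well"` or `"piecewise"`.
#' @param barrier,dg double-well parameters (kcal/mol).
#' @param knots_s,knots_g piecewise knots.
#' @return function mapping normalized s to G (kcal/mol).
#' @export
truth_profile <- function(label = c("double_well", "piecewise"),
                          barrier = 10, dg = -3,
                          knots_s = NULL, knots_g = NULL) {
  label <- match.arg(label)
  if (label == "double_well") {
    check_number(barrier, "barrier", lower = 0)
    check_number(dg, "dg")
    function(s) barrier * sin(pi * s)^2 + dg * s^2 * (3 - 2 * s)
  } else {
    if (is.null(knots_s) || is.null(knots_g) ||
        length(knots_s) != length(knots_g)) {
      stop_invalid("knots_s", "piecewise profile needs matching knots")
    }
    function(s) stats::approx(knots_s, knots_g, xout = s, rule = 2)$y
  }
}

#' Specification of a synthetic FEP window set
#'
#' Defines the ground truth and sampling structure for
#' [generate_fep_windows()]: the truth free-energy profile, the fraction of
#' it carried by the gas-phase QM energies (`qm_fraction`; the remainder is
#' carried by the interaction-energy ensembles), per-window Gaussian noise,
#' and sample counts.
#'
#' @param n_windows number of windows (>= 2).
#' @param truth function s -> G (kcal/mol) over `[0, 1]`, e.g. from
#'   [truth_profile()].
#' @param qm_fraction fraction of the truth carried by gas-phase energies,
#'   in `[0, 1]`.
#' @param noise_sigma per-window interaction-energy standard deviation
#'   (kcal/mol), >= 0.
#' @param n_samples_per_window samples per window (>= 1).
#' @param temperature temperature in K (default 303).
#' @param ar1 AR(1) coefficient of the interaction samples, in `[0, 1)`
#'   (default 0 = i.i.d.).
#' @param seed integer seed.
#' @return An object of class `synthetic_fep_spec`.
#' @export
synthetic_fep_spec <- function(n_windows = 21,
                               truth = truth_profile("double_well"),
                               qm_fraction = 0.5, noise_sigma = 0.5,
                               n_samples_per_window = 2000,
                               temperature = 303, ar1 = 0, seed = 1) {
  n_windows <- check_count(n_windows, "n_windows", min = 2L)
  stopifnot(is.function(truth))
  check_number(qm_fraction, "qm_fraction", lower = 0, upper = 1)
  check_number(noise_sigma, "noise_sigma", lower = 0)
  n_samples_per_window <- check_count(n_samples_per_window,
                                      "n_samples_per_window", min = 1L)
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  check_number(ar1, "ar1", lower = 0, upper = 1)
  if (ar1 >= 1) stop_invalid("ar1", "must be < 1")
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(n_windows = n_windows, truth = truth,
                 qm_fraction = qm_fraction, noise_sigma = noise_sigma,
                 n_samples_per_window = n_samples_per_window,
                 temperature = temperature, ar1 = ar1, seed = seed),
            class = "synthetic_fep_spec")
}

#' Generate synthetic FEP windows with known ground truth
#'
#' Windows sit at evenly spaced path coordinates over `[0, 1]`. The
#' gas-phase QM energies carry `qm_fraction` of the truth profile; the
#' interaction-energy ensembles are Gaussian with standard deviation
#' `noise_sigma` and means constructed so that the *exponential (Zwanzig)
#' average* of consecutive-window differences reproduces the remaining
#' `1 - qm_fraction` share of each truth increment. For a Gaussian ensemble
#' the exponential average of a mean shift `dmu` with spread `sigma` is
#' `dmu - sigma^2 / (2 kB T)`, so each mean increment carries a
#' `+ sigma^2 / (2 kB T)` offset; at `noise_sigma = 0` the mean differences
#' equal the truth increments exactly. Optional AR(1) serial correlation
#' emulates the autocorrelation of real MD window sampling.
#'
#' @param spec a [synthetic_fep_spec()].
#' @return list with `windows` (list of [fep_window()]), and `truth`: a list
#'   with `s`, `G` (truth profile re-zeroed at the first window), `e_qm0`,
#'   `interaction_mean`, `sigma`, `temperature`.
#' @export
generate_fep_windows <- function(spec) {
  stopifnot(inherits(spec, "synthetic_fep_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_windows
    s <- seq(0, 1, length.out = n)
    g <- spec$truth(s)
    g <- g - g[1L]
    e0 <- spec$qm_fraction * g
    kT <- kBT_kcal(spec$temperature)
    dmu <- diff((1 - spec$qm_fraction) * g) +
      spec$noise_sigma^2 / (2 * kT)
    mu <- c(0, cumsum(dmu))
    nsmp <- spec$n_samples_per_window
    windows <- vector("list", n)
    for (i in seq_len(n)) {
      eps <- stats::rnorm(nsmp)
      if (spec$ar1 > 0 && nsmp > 1L) {
        innov_sd <- sqrt(1 - spec$ar1^2)
        for (k in 2:nsmp) {
          eps[k] <- spec$ar1 * eps[k - 1L] + innov_sd * eps[k]
        }
      }
      windows[[i]] <- fep_window(i, s[i], e0[i],
                                 mu[i] + spec$noise_sigma * eps)
    }
    list(windows = windows,
         truth = list(s = s, G = g, e_qm0 = e0, interaction_mean = mu,
                      sigma = spec$noise_sigma,
                      temperature = spec$temperature))
  })
}

# run expr under a seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Specification of synthetic titration data
#'
#' @param pka_true true pKa (pH units).
#' @param hill_true true Hill coefficient, > 0.
#' @param ph_grid strictly increasing pH values.
#' @param n_samples_per_ph Bernoulli draws per pH (>= 1).
#' @param seed integer seed.
#' @return An object of class `synthetic_titration_spec`.
#' @export
synthetic_titration_spec <- function(pka_true = 10.5, hill_true = 1,
                                     ph_grid = seq(6, 14, by = 0.5),
                                     n_samples_per_ph = 5000, seed = 1) {
  check_number(pka_true, "pka_true")
  check_number(hill_true, "hill_true", lower = 0, allow_equal_lower = FALSE)
  ph_grid <- as.numeric(ph_grid)
  if (is.unsorted(ph_grid, strictly = TRUE)) {
    stop_invalid("ph_grid", "must be strictly increasing")
  }
  n_samples_per_ph <- check_count(n_samples_per_ph, "n_samples_per_ph",
                                  min = 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(pka_true = pka_true, hill_true = hill_true,
                 ph_grid = ph_grid, n_samples_per_ph = n_samples_per_ph,
                 seed = seed),
            class = "synthetic_titration_spec")
}

#' Generate Bernoulli titration records along a Hill curve
#'
#' At each pH, `n_samples_per_ph` Bernoulli protonation samples are drawn
#' with protonated probability `1 / (1 + 10^(hill (pH - pKa)))` (base form).
#'
#' @param spec a [synthetic_titration_spec()].
#' @param residue residue label for the series.
#' @return list with `series` (a [titration_series()] with counts) and
#'   `truth` (pKa, hill, and the noiseless fractions).
#' @export
generate_titration <- function(spec, residue = "LYS") {
  stopifnot(inherits(spec, "synthetic_titration_spec"))
  withr_seed(spec$seed, {
    p <- hill_fraction(spec$ph_grid, spec$pka_true, spec$hill_true)
    k <- stats::rbinom(length(p), spec$n_samples_per_ph, p)
    series <- titration_series(spec$ph_grid, k / spec$n_samples_per_ph,
                               counts = rep(spec$n_samples_per_ph,
                                            length(p)),
                               residue = residue)
    list(series = series,
         truth = list(pka = spec$pka_true, hill = spec$hill_true,
                      fraction = p))
  })
}

#' Specification of a synthetic progress curve
#'
#' @param v0 initial rate (uM/h), >= 0.
#' @param k_inact first-order enzyme inactivation rate (1/h), >= 0.
#' @param t_grid time points (h), nonnegative increasing.
#' @param noise_sigma Gaussian concentration noise (uM), >= 0.
#' @param enzyme_uM enzyme concentration (uM), > 0.
#' @param seed integer seed.
#' @return An object of class `synthetic_progress_spec`.
#' @export
synthetic_progress_spec <- function(v0 = 3.33, k_inact = 0.12,
                                    t_grid = c(0, 1.5, 3, 19, 48, 120),
                                    noise_sigma = 0.5, enzyme_uM = 8,
                                    seed = 1) {
  check_number(v0, "v0", lower = 0)
  check_number(k_inact, "k_inact", lower = 0)
  t_grid <- as.numeric(t_grid)
  if (any(t_grid < 0) || is.unsorted(t_grid, strictly = TRUE)) {
    stop_invalid("t_grid", "must be nonnegative strictly increasing")
  }
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(enzyme_uM, "enzyme_uM", lower = 0, allow_equal_lower = FALSE)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(v0 = v0, k_inact = k_inact, t_grid = t_grid,
                 noise_sigma = noise_sigma, enzyme_uM = enzyme_uM,
                 seed = seed),
            class = "synthetic_progress_spec")
}

#' Generate a progress curve with first-order enzyme inactivation
#'
#' Mean curve `P(t) = (v0 / k_inact) (1 - exp(-k_inact t))`, degenerating to
#' `v0 t` when `k_inact = 0`, plus Gaussian noise.
#'
#' @param spec a [synthetic_progress_spec()].
#' @return list with `curve` (a [progress_curve()]) and `truth`
#'   (`v0`, `k_inact`, `plateau`, `tof_s`, noiseless `mean`).
#' @export
generate_progress <- function(spec) {
  stopifnot(inherits(spec, "synthetic_progress_spec"))
  withr_seed(spec$seed, {
    t <- spec$t_grid
    mean_p <- if (spec$k_inact == 0) spec$v0 * t else
      spec$v0 / spec$k_inact * (1 - exp(-spec$k_inact * t))
    p <- mean_p + stats::rnorm(length(t), 0, spec$noise_sigma)
    p[t == 0] <- mean_p[t == 0]        # clean origin
    list(curve = progress_curve(t, p, enzyme_uM = spec$enzyme_uM),
         truth = list(v0 = spec$v0, k_inact = spec$k_inact,
                      plateau = if (spec$k_inact > 0)
                        spec$v0 / spec$k_inact else Inf,
                      tof_s = spec$v0 / 3600 / spec$enzyme_uM,
                      mean = mean_p))
  })
}

#' Specification of a synthetic toy trajectory
#'
#' @param n_frames number of frames (>= 1).
#' @param n_atoms number of atoms (>= 2; atoms 1 and 2 are the tagged pair).
#' @param distance_program target distances (Angstrom) for the tagged pair,
#'   realized piecewise-constant across the frames.
#' @param unbind_frame frame index from which the pair distance exceeds the
#'   unbound bound (>= 15 A), or `NA` for no unbinding.
#' @param noise_sigma Gaussian jitter on the programmed distance (Angstrom),
#'   >= 0 (default 0 = exact realization).
#' @param seed integer seed.
#' @return An object of class `synthetic_trajectory_spec`.
#' @export
synthetic_trajectory_spec <- function(n_frames = 1000, n_atoms = 5,
                                      distance_program = 3.5,
                                      unbind_frame = NA,
                                      noise_sigma = 0, seed = 1) {
  n_frames <- check_count(n_frames, "n_frames", min = 1L)
  n_atoms <- check_count(n_atoms, "n_atoms", min = 2L)
  distance_program <- as.numeric(distance_program)
  if (!length(distance_program) || any(distance_program <= 0)) {
    stop_invalid("distance_program", "must be positive distances")
  }
  if (!is.na(unbind_frame)) {
    unbind_frame <- check_count(unbind_frame, "unbind_frame", min = 1L)
    if (unbind_frame > n_frames) {
      stop_invalid("unbind_frame", "must be <= n_frames")
    }
  }
  check_number(noise_sigma, "noise_sigma", lower = 0)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(n_frames = n_frames, n_atoms = n_atoms,
                 distance_program = distance_program,
                 unbind_frame = unbind_frame, noise_sigma = noise_sigma,
                 seed = seed),
            class = "synthetic_trajectory_spec")
}

#' Generate a toy trajectory realizing a programmed pair distance
#'
#' Atom 1 (`OG`, resid 1) stays at the origin; atom 2 (`C1`, resid 2,
#' ligand) sits on the x axis at the programmed distance (plus optional
#' jitter). From `unbind_frame` on, the pair distance grows past 15 A
#' (ligand release into the solvent). Remaining atoms are static scaffold
#' positions.
#'
#' @param spec a [synthetic_trajectory_spec()].
#' @return list with `traj` (an [md_trajectory()]) and `truth`
#'   (`distance` per frame, `unbind_frame`).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trajectory_spec"))
  withr_seed(spec$seed, {
    n <- spec$n_frames
    target <- rep(spec$distance_program,
                  each = ceiling(n / length(spec$distance_program)))[1:n]
    if (spec$noise_sigma > 0) {
      target <- target + stats::rnorm(n, 0, spec$noise_sigma)
      target <- pmax(target, 0.1)
    }
    if (!is.na(spec$unbind_frame)) {
      i <- spec$unbind_frame:n
      target[i] <- 16 + 0.05 * (i - spec$unbind_frame) +
        if (spec$noise_sigma > 0)
          abs(stats::rnorm(length(i), 0, spec$noise_sigma)) else 0
    }
    scaffold <- matrix(stats::rnorm((spec$n_atoms - 2L) * 3L, 0, 2),
                       ncol = 3L)
    coords <- array(0, c(n, spec$n_atoms, 3L))
    for (f in seq_len(n)) {
      coords[f, 2L, 1L] <- target[f]
      if (spec$n_atoms > 2L) coords[f, 3:spec$n_atoms, ] <- scaffold
    }
    atoms <- data.frame(
      name = c("OG", "C1", paste0("X", seq_len(spec$n_atoms - 2L))),
      element = c("O", "C", rep("C", spec$n_atoms - 2L)),
      resid = c(1L, 2L, rep(3L, spec$n_atoms - 2L)),
      resname = c("SER", "LIG", rep("SCF", spec$n_atoms - 2L))
    )
    list(traj = md_trajectory(coords, atoms = atoms,
                              times = seq_len(n) - 1),
         truth = list(distance = target,
                      unbind_frame = spec$unbind_frame))
  })
}

#' Write a generator truth record as JSON
#'
#' @param truth a truth record list from any generator.
#' @param file output path.
#' @export
write_truth_record <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
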