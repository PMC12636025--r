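#' A rate-constant measurement
#'
#' @param k first-order rate constant (1/s), > 0.
#' @param temperature temperature in K, > 0.
#' @param label optional label.
#' @return An object of class `rate_measurement`.
#' @export
rate_measurement <- function(k, temperature, label = "") {
  check_number(k, "k", lower = 0, allow_equal_lower = FALSE)
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  structure(list(k = k, temperature = temperature,
                 label = as.character(label)),
            class = "rate_measurement")
}

#' Activation free energy from a rate constant (Eyring equation)
#'
#' Inverts the Eyring transition-state-theory relation
#' `k = (kB T / h) exp(-dG / R T)` with transmission coefficient 1:
#' `dG = R T log(kB T / (h k))`.
#'
#' @param k rate constant (1/s) or a [rate_measurement()].
#' @param temperature temperature in K (ignored when `k` is a
#'   `rate_measurement`).
#' @return Activation free energy in kcal/mol.
#' @export
barrier_from_rate <- function(k, temperature = 303) {
  if (inherits(k, "rate_measurement")) {
    temperature <- k$temperature
    k <- k$k
  }
  check_number(k, "k", lower = 0, allow_equal_lower = FALSE)
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  prefactor <- phys_constants$kB_J * temperature / phys_constants$h_J
  phys_constants$R_kcal * temperature * log(prefactor / k)
}

#' Rate constant from an activation free energy (Eyring equation)
#'
#' `k = (kB T / h) exp(-dG / R T)`, transmission coefficient 1.
#'
#' @param dg activation free energy (kcal/mol).
#' @param temperature temperature in K.
#' @return Rate constant in 1/s.
#' @export
rate_from_barrier <- function(dg, temperature = 303) {
  check_number(dg, "dg")
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  prefactor <- phys_constants$kB_J * temperature / phys_constants$h_J
  prefactor * exp(-dg / (phys_constants$R_kcal * temperature))
}

#' Enzyme progress curve
#'
#' Product concentration versus time for a batch reaction, plus the enzyme
#' concentration needed to express per-enzyme turnovers. The enzyme amount
#' may be given directly in uM, or as mass (mg per reaction mL) together
#' with a molar mass (g/mol); the molar mass has no default.
#'
#' @param times time points in hours, nonnegative increasing.
#' @param concentrations product concentrations in uM.
#' @param enzyme_uM enzyme concentration in uM.
#' @param enzyme_mg_per_mL,molar_mass alternative enzyme specification.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(times, concentrations, enzyme_uM = NULL,
                           enzyme_mg_per_mL = NULL, molar_mass = NULL) {
  times <- as.numeric(times)
  concentrations <- as.numeric(concentrations)
  if (length(times) != length(concentrations)) {
    stop_invalid("concentrations", "length must match times")
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop_invalid("times", "must be nonnegative and strictly increasing")
  }
  if (any(!is.finite(concentrations))) {
    stop_invalid("concentrations", "must be finite")
  }
  if (is.null(enzyme_uM)) {
    if (is.null(enzyme_mg_per_mL) || is.null(molar_mass)) {
      stop("supply enzyme_uM, or enzyme_mg_per_mL together with molar_mass")
    }
    # mg/mL = g/L; g/L / (g/mol) = mol/L -> uM
    enzyme_uM <- enzyme_mg_per_mL / molar_mass * 1e6
  }
  check_number(enzyme_uM, "enzyme_uM", lower = 0, allow_equal_lower = FALSE)
  structure(list(times = times, concentrations = concentrations,
                 enzyme_uM = enzyme_uM),
            class = "progress_curve")
}

#' Turnover frequency, total turnover number and inactivation plateau
#'
#' TOF is the least-squares slope of concentration versus time over the
#' initial window, converted to per-second, divided by the enzyme
#' concentration (an apparent kcat). TTN is the final product concentration
#' per enzyme. The plateau is the fitted asymptote of the first-order
#' inactivation model `P(t) = P_inf (1 - exp(-kappa t))`; if the fit does
#' not converge the maximum observed concentration is reported and flagged.
#'
#' @param curve a [progress_curve()].
#' @param initial_window length of the initial-rate window in hours
#'   (default: through the 3rd time point).
#' @return list of class `kinetics_summary`: `tof_s` (1/s), `ttn`,
#'   `plateau_uM`, `k_inact_h` (1/h, NA on fallback), `plateau_fit_converged`,
#'   `slope_uM_h`.
#' @export
tof_ttn <- function(curve, initial_window = NULL) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$times
  p <- curve$concentrations
  if (is.null(initial_window)) initial_window <- t[min(3L, length(t))]
  sel <- t <= initial_window
  if (sum(sel) < 2L) stop("degenerate initial window: fewer than 2 points")
  if (length(unique(t[sel])) < 2L) stop("degenerate initial window")
  slope <- unname(stats::coef(stats::lm(p[sel] ~ t[sel]))[2L])
  tof_s <- slope / 3600 / curve$enzyme_uM
  ttn <- p[length(p)] / curve$enzyme_uM

  plateau <- max(p)
  k_inact <- NA_real_
  converged <- FALSE
  if (length(t) >= 3L && stats::sd(p) > 0) {
    p_inf0 <- max(p)
    k0 <- if (p_inf0 > 0 && slope > 0) slope / p_inf0 else 1 / max(t[t > 0], 1)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        pp ~ p_inf * (1 - exp(-kappa * tt)),
        data = data.frame(tt = t, pp = p),
        start = list(p_inf = p_inf0, kappa = max(k0, 1e-6)),
        lower = c(p_inf = 0, kappa = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      plateau <- unname(cf["p_inf"])
      k_inact <- unname(cf["kappa"])
      converged <- TRUE
    }
  }
  structure(list(tof_s = tof_s, ttn = ttn, plateau_uM = plateau,
                 k_inact_h = k_inact, plateau_fit_converged = converged,
                 slope_uM_h = slope),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf("TOF %.3g 1/s | TTN %.3g | plateau %.3g uM (%s)\n",
              x$tof_s, x$ttn, x$plateau_uM,
              if (x$plateau_fit_converged) "fitted" else "max observed"))
  invisible(x)
}

#' Reaction rate from an absorbance slope (Beer-Lambert)
#'
#' @param slope absorbance change rate (AU/min).
#' @param epsilon molar extinction coefficient (1/mM/cm), > 0.
#' @param pathlength optical path length (cm), > 0 (default 1).
#' @return rate in mM/min.
#' @export
rate_from_absorbance <- function(slope, epsilon, pathlength = 1) {
  check_number(slope, "slope")
  check_number(epsilon, "epsilon", lower = 0, allow_equal_lower = FALSE)
  check_number(pathlength, "pathlength", lower = 0,
               allow_equal_lower = FALSE)
  slope / (epsilon * pathlength)
}

#' Read a progress curve from CSV
#'
#' Columns: `time_h`, `conc_uM`.
#'
#' @param file path.
#' @param enzyme_uM enzyme concentration in uM.
#' @inheritParams progress_curve
#' @return a [progress_curve()].
#' @export
read_progress_curve <- function(file, enzyme_uM = NULL,
                                enzyme_mg_per_mL = NULL, molar_mass = NULL) {
  d <- utils::read.csv(file, comment.char = "#")
  progress_curve(d$time_h, d$conc_uM, enzyme_uM = enzyme_uM,
                 enzyme_mg_per_mL = enzyme_mg_per_mL,
                 molar_mass = molar_mass)
}
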