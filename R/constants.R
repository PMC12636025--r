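#' Physical constants used throughout the package
#'
#' CODATA-2018 exact values. All package energies are kcal/mol, lengths are
#' Angstrom, masses are amu, wavenumbers are cm^-1, temperatures are K.
#'
#' @format A named list:
#' \describe{
#'   \item{kB_J}{Boltzmann constant, J/K}
#'   \item{h_J}{Planck constant, J s}
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{c_cm}{speed of light, cm/s}
#'   \item{R_kcal}{molar gas constant, kcal/(mol K)}
#'   \item{J_per_kcal}{Joule per thermochemical kcal}
#'   \item{kcal_per_wavenumber}{kcal/mol carried by 1 cm^-1 (h c N_A)}
#'   \item{wavenumber_factor}{cm^-1 per sqrt(kcal mol^-1 A^-2 amu^-1),
#'     converting mass-weighted Hessian eigenvalues to wavenumbers}
#' }
#' @export
phys_constants <- local({
  kB_J <- 1.380649e-23
  h_J  <- 6.62607015e-34
  N_A  <- 6.02214076e23
  c_cm <- 2.99792458e10
  J_per_kcal <- 4184
  list(
    kB_J = kB_J,
    h_J  = h_J,
    N_A  = N_A,
    c_cm = c_cm,
    R_kcal = kB_J * N_A / J_per_kcal,
    J_per_kcal = J_per_kcal,
    kcal_per_wavenumber = h_J * c_cm * N_A / J_per_kcal,
    # eigenvalue lambda in kcal mol^-1 A^-2 amu^-1:
    # omega^2 [s^-2] = lambda * J_per_kcal * 1e23  (1 amu = 1e-3/N_A kg)
    wavenumber_factor = sqrt(J_per_kcal * 1e23) / (2 * pi * c_cm)
  )
})

# kB*T in kcal/mol
kBT_kcal <- function(temperature) phys_constants$R_kcal * temperature

# standard atomic masses (amu) for XYZ element lookup
.atomic_masses <- c(
  H = 1.008, D = 2.014, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.90
)

#' Look up standard atomic masses from element symbols
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in amu.
#' @export
element_masses <- function(elements) {
  key <- paste0(toupper(substr(elements, 1, 1)),
                tolower(substr(elements, 2, nchar(elements))))
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

# --- small internal validators ------------------------------------------------

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (x < lower || (!allow_equal_lower && x == lower) || x > upper) {
    stop_invalid(field, sprintf("must be in %s%g, %g]",
                                if (allow_equal_lower) "[" else "(",
                                lower, upper))
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_invalid(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}
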