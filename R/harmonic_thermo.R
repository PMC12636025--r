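#' Hessian block of a QM subsystem
#'
#' Symmetric matrix of second derivatives of the energy with respect to the
#' Cartesian coordinates of the QM atoms, in kcal/mol/A^2, plus per-atom
#' masses. Set `mass_weighted = TRUE` when the matrix is already
#' mass-weighted (units kcal/mol/A^2/amu).
#'
#' @param matrix square symmetric numeric matrix, dimension 3 * n_atoms.
#' @param masses numeric vector of atomic masses (amu), length n_atoms.
#' @param mass_weighted logical; skip mass weighting when `TRUE`.
#' @param tol relative symmetry tolerance (default 1e-6).
#' @return An object of class `hessian_block`.
#' @export
hessian_block <- function(matrix, masses, mass_weighted = FALSE,
                          tol = 1e-6) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop_invalid("matrix", "must be square")
  scale <- max(abs(matrix), 1e-300)
  if (max(abs(matrix - t(matrix))) > tol * scale) {
    stop("hessian asymmetric beyond tolerance")
  }
  masses <- as.numeric(masses)
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    stop_invalid("masses", "must be positive and finite")
  }
  # masses are per atom (dim = 3 * n_atoms) for Cartesian Hessians, or per
  # coordinate (dim = n) for reduced/toy oscillator blocks
  if (nrow(matrix) == 3L * length(masses)) {
    coord_masses <- rep(masses, each = 3L)
  } else if (nrow(matrix) == length(masses)) {
    coord_masses <- masses
  } else {
    stop_invalid("matrix",
                 "dimension must equal 3 * n_atoms (or one mass per coordinate)")
  }
  structure(list(matrix = (matrix + t(matrix)) / 2, masses = masses,
                 coord_masses = coord_masses,
                 mass_weighted = isTRUE(mass_weighted)),
            class = "hessian_block")
}

# Eckart projector removing rigid translations (and rotations when coords
# given) from a mass-weighted Hessian
tr_projector <- function(masses, coords = NULL) {
  n <- length(masses)
  sm <- sqrt(masses)
  basis <- matrix(0, 3L * n, 0L)
  for (ax in 1:3) {
    v <- numeric(3L * n)
    v[seq(ax, 3L * n, by = 3L)] <- sm
    basis <- cbind(basis, v)
  }
  if (!is.null(coords)) {
    com <- colSums(coords * masses) / sum(masses)
    xc <- sweep(coords, 2L, com)
    for (ax in 1:3) {
      e <- diag(3)[, ax]
      rot <- t(vapply(seq_len(n), function(j) {
        sm[j] * c(e[2] * xc[j, 3] - e[3] * xc[j, 2],
                  e[3] * xc[j, 1] - e[1] * xc[j, 3],
                  e[1] * xc[j, 2] - e[2] * xc[j, 1])
      }, numeric(3)))
      basis <- cbind(basis, as.vector(t(rot)))
    }
  }
  q <- qr(basis)
  qb <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  diag(3L * n) - qb %*% t(qb)
}

#' Harmonic normal modes of a Hessian block
#'
#' Mass-weights the Hessian (unless already mass-weighted), optionally
#' projects out rigid translations and rotations (Eckart projection;
#' rotations require `coords`), diagonalizes, and converts eigenvalues to
#' wavenumbers: `sign(lambda) * sqrt(|lambda|) * conversion`. Negative
#' wavenumbers encode imaginary modes. The stationary point is classified by
#' the count of imaginary modes (below `-imag_tol`): 0 = minimum,
#' 1 = transition_state, >= 2 = higher_order. Modes with
#' `|wavenumber| < imag_tol` are flagged near-zero and excluded from
#' thermochemistry.
#'
#' @param hessian a [hessian_block()].
#' @param project_tr project out rigid translations/rotations (default
#'   `FALSE`).
#' @param coords optional n_atoms x 3 coordinate matrix (A), needed to
#'   project rotations; with `coords = NULL` only translations are projected.
#' @param imag_tol wavenumber magnitude (cm^-1) below which a mode counts as
#'   near-zero (default 5).
#' @return An object of class `normal_modes`: list with `wavenumbers`
#'   (cm^-1, ascending), `classification`, `n_imaginary`, `near_zero`
#'   (logical mask).
#' @export
normal_modes <- function(hessian, project_tr = FALSE, coords = NULL,
                         imag_tol = 5) {
  stopifnot(inherits(hessian, "hessian_block"))
  h <- hessian$matrix
  if (!hessian$mass_weighted) {
    sm <- sqrt(hessian$coord_masses)
    h <- h / outer(sm, sm)
  }
  if (project_tr) {
    if (length(hessian$coord_masses) != 3L * length(hessian$masses)) {
      stop("TR projection needs a Cartesian Hessian (per-atom masses)")
    }
    p <- tr_projector(hessian$masses, coords)
    h <- p %*% h %*% p
  }
  lam <- eigen((h + t(h)) / 2, symmetric = TRUE, only.values = TRUE)$values
  wn <- sign(lam) * sqrt(abs(lam)) * phys_constants$wavenumber_factor
  wn <- sort(wn)
  near_zero <- abs(wn) < imag_tol
  n_imag <- sum(wn < -imag_tol)
  classification <- if (n_imag == 0L) "minimum"
                    else if (n_imag == 1L) "transition_state"
                    else "higher_order"
  structure(list(wavenumbers = wn, classification = classification,
                 n_imaginary = n_imag, near_zero = near_zero,
                 imag_tol = imag_tol),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("Normal modes: %d (%d imaginary) -> %s\n",
              length(x$wavenumbers), x$n_imaginary, x$classification))
  cat("wavenumbers (cm^-1):",
      paste(sprintf("%.1f", x$wavenumbers), collapse = ", "), "\n")
  invisible(x)
}

real_modes <- function(modes) {
  modes$wavenumbers[modes$wavenumbers > 0 & !modes$near_zero]
}

#' Zero-point vibrational energy
#'
#' `sum over real modes of h c nu / 2` per mole, in kcal/mol. Imaginary and
#' near-zero modes are excluded.
#'
#' @param modes a [normal_modes()] object.
#' @return ZPE in kcal/mol.
#' @export
zpe <- function(modes) {
  stopifnot(inherits(modes, "normal_modes"))
  sum(real_modes(modes)) / 2 * phys_constants$kcal_per_wavenumber
}

#' Quantum-harmonic vibrational free energy
#'
#' `sum over real modes of [h c nu / 2 + kB T log(1 - exp(-h c nu / kB T))]`
#' per mole, in kcal/mol. Modes below `thermal_floor` contribute their ZPE
#' but are excluded from the thermal (log) term, which diverges as nu -> 0.
#'
#' @param modes a [normal_modes()] object.
#' @param temperature temperature in K.
#' @param thermal_floor wavenumber floor (cm^-1) for the thermal term
#'   (default 20).
#' @return Vibrational free energy in kcal/mol.
#' @export
vib_free_energy <- function(modes, temperature = 303, thermal_floor = 20) {
  stopifnot(inherits(modes, "normal_modes"))
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  nu <- real_modes(modes)
  if (!length(nu)) return(0)
  e <- nu * phys_constants$kcal_per_wavenumber   # h c nu per mole
  kT <- kBT_kcal(temperature)
  thermal <- ifelse(nu >= thermal_floor, kT * log1p(-exp(-e / kT)), 0)
  sum(e / 2 + thermal)
}

# --- Hessian text I/O ---------------------------------------------------------

#' Read a Hessian block from a plain-text file
#'
#' Format: a header line `masses: m1 m2 ...`, then the symmetric matrix,
#' one row per line, whitespace-separated, kcal/mol/A^2.
#'
#' @param file path.
#' @return a [hessian_block()].
#' @export
read_hessian <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!grepl("^masses:", lines[1L])) {
    stop("malformed hessian file: expected 'masses:' header")
  }
  masses <- as.numeric(strsplit(trimws(sub("^masses:", "", lines[1L])),
                                "\\s+")[[1L]])
  rows <- lapply(lines[-1L],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  hessian_block(do.call(rbind, rows), masses)
}

#' Write a Hessian block to a plain-text file
#'
#' @param hessian a [hessian_block()].
#' @param file output path.
#' @export
write_hessian <- function(hessian, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("masses:", paste(hessian$masses, collapse = " ")), con)
  utils::write.table(hessian$matrix, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
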