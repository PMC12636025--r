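#' QM-subsystem structure
#'
#' A single structure of the quantum subsystem: atom labels, Cartesian
#' coordinates in Angstrom and atomic masses in amu. Building block of an
#' IRC-style reaction path.
#'
#' @param coords numeric n x 3 matrix of coordinates (Angstrom).
#' @param masses numeric vector of atomic masses (amu); inferred from
#'   `labels` via [element_masses()] when `NULL`.
#' @param labels character atom labels (element symbols when `masses` is
#'   `NULL`).
#' @return An object of class `qm_structure`.
#' @export
qm_structure <- function(coords, masses = NULL, labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 1L) {
    stop_invalid("coords", "must be an n x 3 matrix with n >= 1")
  }
  if (!all(is.finite(coords))) stop_invalid("coords", "must be finite")
  if (is.null(labels)) labels <- rep("X", nrow(coords))
  if (is.null(masses)) masses <- element_masses(labels)
  masses <- as.numeric(masses)
  if (length(masses) != nrow(coords) || any(!is.finite(masses)) ||
      any(masses <= 0)) {
    stop_invalid("masses", "must be positive, finite, one per atom")
  }
  structure(list(coords = coords, masses = masses,
                 labels = as.character(labels)),
            class = "qm_structure")
}

#' Ordered IRC reaction path
#'
#' @param structures list of [qm_structure()] objects sharing atom count and
#'   masses.
#' @param s optional precomputed path coordinate (amu^1/2 Angstrom),
#'   nondecreasing with `s[1] == 0`.
#' @return An object of class `irc_path`.
#' @export
irc_path <- function(structures, s = NULL) {
  if (!length(structures)) stop_invalid("structures", "empty path")
  n_at <- vapply(structures, function(x) nrow(x$coords), integer(1))
  if (length(unique(n_at)) != 1L) {
    stop("conformability error: structures differ in atom count")
  }
  m0 <- structures[[1L]]$masses
  same <- vapply(structures, function(x) isTRUE(all.equal(x$masses, m0)),
                 logical(1))
  if (!all(same)) stop("conformability error: structures differ in masses")
  if (!is.null(s)) {
    s <- as.numeric(s)
    if (length(s) != length(structures) || s[1L] != 0 ||
        any(diff(s) < 0)) {
      stop_invalid("s", "must match path length, start at 0, be nondecreasing")
    }
  }
  structure(list(structures = structures, s = s), class = "irc_path")
}

#' Cumulative mass-weighted path coordinate along an IRC path
#'
#' The distance between consecutive structures is the mass-weighted Cartesian
#' displacement `sqrt(sum_j m_j * |r_j(i) - r_j(i-1)|^2)`; the path coordinate
#' is its cumulative sum, anchored at `s[1] = 0`. Units: amu^1/2 Angstrom.
#' Structures are assumed to sit in a common frame (as IRC frames do); no
#' superposition is applied.
#'
#' @param path an [irc_path()], or a list of [qm_structure()] objects.
#' @return numeric vector of path-coordinate values, one per structure.
#' @export
path_coordinate <- function(path) {
  if (inherits(path, "qm_structure")) path <- list(path)
  if (!inherits(path, "irc_path")) path <- irc_path(path)
  structures <- path$structures
  n <- length(structures)
  if (n == 1L) return(0)
  m <- structures[[1L]]$masses
  inc <- vapply(seq_len(n - 1L), function(i) {
    d <- structures[[i + 1L]]$coords - structures[[i]]$coords
    sqrt(sum(m * rowSums(d * d)))
  }, numeric(1))
  c(0, cumsum(inc))
}

# --- multi-frame XYZ I/O ------------------------------------------------------

#' Read a multi-frame XYZ file
#'
#' Standard XYZ: atom count line, comment line, then `element x y z` records,
#' frames concatenated.
#'
#' @param file path to an XYZ file.
#' @return list with `elements` (character) and `coords`
#'   (list of n x 3 matrices, one per frame).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  # trailing blank lines are tolerated; comment lines may be blank
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  frames <- list()
  elements <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ: bad atom count at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[[`, character(1), 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (is.null(elements)) elements <- el
    else if (!identical(el, elements)) {
      stop("malformed XYZ: element roster changes between frames")
    }
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  list(elements = elements, coords = frames)
}

#' Write a multi-frame XYZ file
#'
#' @param elements character element symbols.
#' @param coords list of n x 3 coordinate matrices (or a single matrix).
#' @param file output path.
#' @param comment comment line (recycled over frames).
#' @export
write_xyz <- function(elements, coords, file, comment = "") {
  if (is.matrix(coords)) coords <- list(coords)
  comment <- rep_len(comment, length(coords))
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_along(coords)) {
    xyz <- coords[[f]]
    writeLines(c(as.character(length(elements)), comment[f]), con)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f",
                       elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(file)
}

#' Build an IRC path from a multi-frame XYZ file
#'
#' Masses are inferred from element symbols.
#'
#' @param file path to a multi-frame XYZ file.
#' @return an [irc_path()].
#' @export
read_irc_path <- function(file) {
  xyz <- read_xyz(file)
  m <- element_masses(xyz$elements)
  irc_path(lapply(xyz$coords, qm_structure, masses = m,
                  labels = xyz$elements))
}
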