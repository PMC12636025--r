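#' MD-style trajectory container
#'
#' Frames of labelled atom coordinates with a constant atom roster.
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   list of `n_atoms x 3` matrices.
#' @param atoms data.frame with columns `name`, `element`, `resid`,
#'   `resname` (missing columns are filled with defaults).
#' @param times optional per-frame time stamps (ns), nondecreasing.
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(coords, atoms = NULL, times = NULL) {
  if (is.list(coords)) {
    n_at <- unique(vapply(coords, nrow, integer(1)))
    if (length(n_at) != 1L) stop_invalid("coords", "atom roster changes")
    arr <- array(0, c(length(coords), n_at, 3L))
    for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 3L) {
    stop_invalid("coords", "must be an n_frames x n_atoms x 3 array")
  }
  n_frames <- dim(coords)[1L]
  n_atoms <- dim(coords)[2L]
  if (is.null(atoms)) atoms <- data.frame(row = seq_len(n_atoms))
  if (is.null(atoms$name)) atoms$name <- paste0("A", seq_len(n_atoms))
  if (is.null(atoms$element)) atoms$element <- "C"
  if (is.null(atoms$resid)) atoms$resid <- seq_len(n_atoms)
  if (is.null(atoms$resname)) atoms$resname <- "RES"
  atoms <- atoms[, c("name", "element", "resid", "resname")]
  if (nrow(atoms) != n_atoms) stop_invalid("atoms", "row count mismatch")
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != n_frames || is.unsorted(times)) {
      stop_invalid("times", "must be nondecreasing, one per frame")
    }
  }
  structure(list(coords = coords, atoms = atoms, times = times,
                 n_frames = n_frames, n_atoms = n_atoms),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms\n",
              x$n_frames, x$n_atoms))
  invisible(x)
}

#' Select atom indices by name / residue / element
#'
#' Inclusive matching: each supplied criterion restricts the selection.
#'
#' @param traj an [md_trajectory()].
#' @param name,resid,resname,element optional vectors of admissible values.
#' @return integer atom indices.
#' @export
select_atoms <- function(traj, name = NULL, resid = NULL, resname = NULL,
                         element = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  keep <- rep(TRUE, traj$n_atoms)
  a <- traj$atoms
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(element)) keep <- keep & a$element %in% element
  which(keep)
}

# n_atoms x 3 coordinate matrix of one frame
frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3L)
}

# resolve an atom argument (index or name) to one index
resolve_atom <- function(traj, atom) {
  if (is.numeric(atom)) {
    atom <- as.integer(atom)
    if (atom < 1L || atom > traj$n_atoms) stop("unknown atom index ", atom)
    return(atom)
  }
  i <- which(traj$atoms$name == atom)
  if (length(i) != 1L) {
    stop("unknown or ambiguous atom name '", atom, "'")
  }
  i
}

# histogram summary shared by the series operations
series_summary <- function(values, bin_width, times = NULL) {
  finite <- values[is.finite(values)]
  if (length(finite)) {
    lo <- floor(min(finite) / bin_width) * bin_width
    hi <- ceiling(max(finite) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    edges <- seq(lo, hi, by = bin_width)
    counts <- as.vector(table(cut(finite, breaks = edges,
                                  include.lowest = TRUE)))
  } else {
    edges <- c(0, bin_width)
    counts <- 0L
  }
  mode_bin <- which.max(counts)
  structure(list(values = values, times = times, edges = edges,
                 counts = counts,
                 mode = (edges[mode_bin] + edges[mode_bin + 1L]) / 2),
            class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("series: %d frames, mode bin at %.3g, range [%.3g, %.3g]\n",
              length(x$values), x$mode,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Interatomic distance time series
#'
#' @param traj an [md_trajectory()].
#' @param atom_a,atom_b atom indices or unique atom names.
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @return A `series_summary`: per-frame values, histogram (edges, counts),
#'   mode bin centre.
#' @export
distance_series <- function(traj, atom_a, atom_b, bin_width = 0.1) {
  i <- resolve_atom(traj, atom_a)
  j <- resolve_atom(traj, atom_b)
  d <- sqrt(rowSums((traj$coords[, i, , drop = FALSE] -
                       traj$coords[, j, , drop = FALSE])^2))
  series_summary(as.vector(d), bin_width, traj$times)
}

# signed dihedral (degrees, wrapped to (-180, 180]); NA when degenerate
dihedral_one <- function(p1, p2, p3, p4, tol = 1e-10) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < tol || sum(n2^2) < tol) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2) / b2n, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral-angle time series
#'
#' Standard signed dihedral over four atoms, in degrees wrapped to
#' `(-180, 180]`. Degenerate (collinear) geometries yield `NA` for that
#' frame.
#'
#' @param traj an [md_trajectory()].
#' @param atoms vector of four atom indices or names.
#' @param bin_width histogram bin width in degrees (default 5).
#' @return A `series_summary`.
#' @export
dihedral_series <- function(traj, atoms, bin_width = 5) {
  idx <- vapply(atoms, function(a) resolve_atom(traj, a), integer(1))
  if (length(idx) != 4L || anyDuplicated(idx)) {
    stop_invalid("atoms", "need four distinct atoms")
  }
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    dihedral_one(traj$coords[f, idx[1L], ], traj$coords[f, idx[2L], ],
                 traj$coords[f, idx[3L], ], traj$coords[f, idx[4L], ])
  }, numeric(1))
  series_summary(vals, bin_width, traj$times)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Rotation + translation of `mobile` minimizing the RMSD to `reference`
#' over paired rows, by SVD of the covariance matrix with the usual
#' reflection guard.
#'
#' @param reference,mobile n x 3 coordinate matrices, paired rows.
#' @return list with `coords` (superposed mobile), `rotation`, `rmsd`.
#' @export
kabsch <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  stopifnot(ncol(reference) == 3L, all(dim(reference) == dim(mobile)),
            nrow(reference) >= 1L)
  cr <- colMeans(reference); cm <- colMeans(mobile)
  p <- sweep(mobile, 2L, cm); q <- sweep(reference, 2L, cr)
  sv <- svd(t(p) %*% q)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(p %*% t(rot), 2L, cr, `+`)
  list(coords = fitted, rotation = rot,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

#' RMSD between two frames over a selection
#'
#' With `superpose = TRUE` (default) an optimal Kabsch superposition on the
#' selection precedes the measurement; otherwise the raw coordinate RMSD is
#' returned.
#'
#' @param reference,frame n x 3 coordinate matrices (full rosters, paired).
#' @param selection integer atom indices (default: all atoms).
#' @param superpose logical.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(reference, frame, selection = NULL, superpose = TRUE) {
  reference <- as.matrix(reference); frame <- as.matrix(frame)
  if (is.null(selection)) selection <- seq_len(nrow(reference))
  if (!length(selection)) stop("empty selection")
  a <- reference[selection, , drop = FALSE]
  b <- frame[selection, , drop = FALSE]
  if (superpose) kabsch(a, b)$rmsd
  else sqrt(mean(rowSums((b - a)^2)))
}

#' Per-residue RMSD after a single global superposition
#'
#' Superposes `frame` onto `reference` once, on `fit_selection`, then
#' reports the RMSD of each residue's atoms without further fitting.
#'
#' @param traj an [md_trajectory()] providing the atom roster (residue ids).
#' @param reference,frame frame indices into `traj`, or n x 3 matrices.
#' @param fit_selection atom indices used for the global fit (default all).
#' @return data.frame with columns `resid`, `resname`, `rmsd`.
#' @export
per_residue_rmsd <- function(traj, reference, frame, fit_selection = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  getf <- function(x) if (is.matrix(x)) x else frame_coords(traj, x)
  ref <- getf(reference); mob <- getf(frame)
  if (is.null(traj$atoms$resid)) stop("missing residue ids")
  if (is.null(fit_selection)) fit_selection <- seq_len(traj$n_atoms)
  fit <- kabsch(ref[fit_selection, , drop = FALSE],
                mob[fit_selection, , drop = FALSE])
  # apply the global transform to the whole roster
  cm <- colMeans(mob[fit_selection, , drop = FALSE])
  cr <- colMeans(ref[fit_selection, , drop = FALSE])
  mob_fit <- sweep(sweep(mob, 2L, cm) %*% t(fit$rotation), 2L, cr, `+`)
  sq <- rowSums((mob_fit - ref)^2)
  agg <- stats::aggregate(sq, list(resid = traj$atoms$resid), mean)
  rn <- traj$atoms$resname[match(agg$resid, traj$atoms$resid)]
  data.frame(resid = agg$resid, resname = rn, rmsd = sqrt(agg$x))
}

#' Water occupancy of a site and exchange events
#'
#' Counts water oxygens within `cutoff` of the centroid of a site selection
#' in every frame. An exchange event is a frame where the identity set of
#' site waters changes while the count stays constant.
#'
#' @param traj an [md_trajectory()].
#' @param site_selection integer atom indices defining the site centroid.
#' @param cutoff distance cutoff in Angstrom.
#' @param water_resnames residue names recognized as water.
#' @return list with `counts` (per frame), `exchange_events` (frame
#'   indices), `water_indices` (per-frame list of resident water resids).
#' @export
water_occupancy <- function(traj, site_selection, cutoff,
                            water_resnames = c("HOH", "WAT", "TIP3",
                                               "SOL")) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (!length(site_selection)) stop("empty selection")
  wat_o <- which(traj$atoms$resname %in% water_resnames &
                   (traj$atoms$element == "O" |
                      traj$atoms$name %in% c("O", "OW", "OH2")))
  if (!length(wat_o)) {
    warning("no water oxygens in the atom roster")
    return(list(counts = rep(0L, traj$n_frames),
                exchange_events = integer(0),
                water_indices = rep(list(integer(0)), traj$n_frames)))
  }
  resident <- vector("list", traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    xyz <- frame_coords(traj, f)
    centroid <- colMeans(xyz[site_selection, , drop = FALSE])
    d <- sqrt(rowSums(sweep(xyz[wat_o, , drop = FALSE], 2L, centroid)^2))
    resident[[f]] <- sort(traj$atoms$resid[wat_o[d <= cutoff]])
  }
  counts <- lengths(resident)
  ex <- which(vapply(seq_len(traj$n_frames)[-1L], function(f) {
    counts[f] == counts[f - 1L] &&
      !identical(resident[[f]], resident[[f - 1L]])
  }, logical(1))) + 1L
  list(counts = as.integer(counts), exchange_events = ex,
       water_indices = resident)
}

#' Detect a persistent threshold crossing (unbinding event)
#'
#' First frame from which the series exceeds `threshold` for at least
#' `persistence` consecutive frames; `NA` when no such run exists.
#'
#' @param series a `series_summary` (from [distance_series()]) or a numeric
#'   vector.
#' @param threshold distance threshold (Angstrom), default 10.
#' @param persistence minimum run length in frames, >= 1 (default 50).
#' @return frame index, or `NA` if never.
#' @export
detect_unbinding <- function(series, threshold = 10, persistence = 50) {
  persistence <- check_count(persistence, "persistence", min = 1L)
  v <- if (inherits(series, "series_summary")) series$values else
    as.numeric(series)
  above <- !is.na(v) & v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= persistence)
  if (!length(hit)) return(NA_integer_)
  starts[hit[1L]]
}

# --- minimal multi-model PDB I/O ----------------------------------------------

#' Read a minimal multi-model PDB file into a trajectory
#'
#' ATOM/HETATM records per the standard fixed columns; MODEL/ENDMDL separate
#' frames (a file without MODEL records is one frame). Alternate locations
#' keep the first variant; insertion codes are not handled.
#'
#' @param file path.
#' @return an [md_trajectory()].
#' @export
read_pdb_trajectory <- function(file) {
  lines <- readLines(file)
  frames <- list()
  cur <- NULL
  atoms <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur)) {
      frames[[length(frames) + 1L]] <<- as.matrix(cur[, c("x", "y", "z")])
      if (is.null(atoms)) atoms <<- cur[, c("name", "element", "resid",
                                            "resname")]
      cur <<- NULL
    }
  }
  for (ln in lines) {
    rec <- substr(ln, 1, 6)
    if (rec == "MODEL ") {
      flush()
    } else if (substr(rec, 1, 4) %in% c("ATOM", "HETA")) {
      alt <- substr(ln, 17, 17)
      if (!alt %in% c(" ", "A", "1")) next
      row <- data.frame(
        name = trimws(substr(ln, 13, 16)),
        resname = trimws(substr(ln, 18, 20)),
        resid = as.integer(trimws(substr(ln, 23, 26))),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        element = trimws(substr(ln, 77, 78)),
        stringsAsFactors = FALSE
      )
      if (row$element == "") {
        row$element <- toupper(substr(gsub("[0-9]", "", row$name), 1, 1))
      }
      cur <- if (is.null(cur)) row else rbind(cur, row)
    } else if (rec %in% c("ENDMDL", "END   ")) {
      flush()
    }
  }
  flush()
  if (!length(frames)) stop("no ATOM/HETATM records in ", file)
  md_trajectory(frames, atoms = atoms)
}

#' Write a trajectory as a minimal multi-model PDB file
#'
#' @param traj an [md_trajectory()].
#' @param file output path.
#' @export
write_pdb_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  a <- traj$atoms
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("MODEL %8d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$resname %in% c("HOH", "WAT", "LIG"), "HETATM", "ATOM"),
      seq_len(traj$n_atoms), substr(a$name, 1, 4), " ",
      substr(a$resname, 1, 3), "A", a$resid, " ",
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(a$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

#' Read a multi-frame XYZ file into a trajectory
#'
#' @param file path.
#' @return an [md_trajectory()].
#' @export
read_xyz_trajectory <- function(file) {
  xyz <- read_xyz(file)
  md_trajectory(xyz$coords,
                atoms = data.frame(name = paste0(xyz$elements,
                                                 seq_along(xyz$elements)),
                                   element = xyz$elements))
}
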