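#' One reaction-path FEP window
#'
#' A window along the IRC path: its path coordinate, the gas-phase QM energy
#' of the frozen QM structure, and an ensemble of QM/MM interaction energies
#' sampled over MM configurations with the QM atoms frozen.
#'
#' @param index integer window index.
#' @param s path coordinate (amu^1/2 Angstrom).
#' @param e_qm0 gas-phase QM energy (kcal/mol).
#' @param samples numeric vector of QM/MM interaction energies (kcal/mol).
#' @return An object of class `fep_window`.
#' @export
fep_window <- function(index, s, e_qm0, samples) {
  check_number(s, "s")
  check_number(e_qm0, "e_qm0")
  samples <- as.numeric(samples)
  if (!length(samples) || any(!is.finite(samples))) {
    stop_invalid("samples", "must be a nonempty finite numeric vector")
  }
  structure(list(index = as.integer(index), s = s, e_qm0 = e_qm0,
                 samples = samples),
            class = "fep_window")
}

#' Free-energy increment of one FEP window by exponential averaging
#'
#' Evaluates the Zwanzig estimator
#' `-kB T log < exp(-dE / kB T) >` on a sample of perturbation energy
#' differences `dE`, via an overflow-safe log-sum-exp. Under
#' `convention = "as_printed"` the sign inside the exponential is flipped
#' (`-kB T log < exp(+dE / kB T) >`), the literal form some papers print.
#'
#' @param delta_e numeric vector of energy differences (kcal/mol).
#' @param temperature temperature in K.
#' @param convention `"zwanzig"` (default) or `"as_printed"`.
#' @return Free-energy increment in kcal/mol.
#' @export
zwanzig_increment <- function(delta_e, temperature = 303,
                              convention = c("zwanzig", "as_printed")) {
  convention <- match.arg(convention)
  check_number(temperature, "temperature", lower = 0, allow_equal_lower = FALSE)
  delta_e <- as.numeric(delta_e)
  if (!length(delta_e) || any(!is.finite(delta_e))) {
    stop_invalid("delta_e", "must be a nonempty finite numeric vector")
  }
  kT <- kBT_kcal(temperature)
  x <- if (convention == "zwanzig") -delta_e / kT else delta_e / kT
  m <- max(x)
  # -kT * log mean exp(x), stabilized
  -kT * (m + log(mean(exp(x - m))))
}

#' Standard error of a window free-energy increment
#'
#' First-order (delta-method) propagation of the variance of
#' `exp(-dE / kB T)` into the log-average, with the effective sample size
#' taken from block averaging: the samples are cut into `blocks` contiguous
#' blocks and the variance of block means of the exponential is used, which
#' inflates the error in the presence of serial correlation. Fewer than 20
#' samples fall back to the naive i.i.d. estimate with a warning.
#'
#' @inheritParams zwanzig_increment
#' @param blocks number of blocks for block averaging (default 10).
#' @return Standard error in kcal/mol.
#' @export
window_error <- function(delta_e, temperature = 303, blocks = 10,
                         convention = c("zwanzig", "as_printed")) {
  convention <- match.arg(convention)
  check_number(temperature, "temperature", lower = 0, allow_equal_lower = FALSE)
  blocks <- check_count(blocks, "blocks", min = 2L)
  delta_e <- as.numeric(delta_e)
  n <- length(delta_e)
  if (n < 2L) stop("window_error needs at least 2 samples")
  kT <- kBT_kcal(temperature)
  x <- if (convention == "zwanzig") -delta_e / kT else delta_e / kT
  m <- max(x)
  w <- exp(x - m)                    # scaled exponentials; scale cancels below
  wbar <- mean(w)
  if (stats::var(w) == 0) return(0)
  if (n < 20L) {
    warning("fewer than 20 samples: naive standard error (no block averaging)")
    se_mean <- stats::sd(w) / sqrt(n)
  } else {
    idx <- cut(seq_len(n), breaks = blocks, labels = FALSE)
    bm <- tapply(w, idx, mean)
    se_mean <- stats::sd(bm) / sqrt(length(bm))
  }
  # delta method on g = -kT log(wbar): |dg/dwbar| = kT / wbar
  kT * se_mean / wbar
}

# surrogate dE for window i -> i+1 when only each window's own samples exist:
# window i's fluctuations recentred on the mean shift between the windows
surrogate_delta_e <- function(w_i, w_next) {
  (w_i$samples - mean(w_i$samples)) +
    (mean(w_next$samples) - mean(w_i$samples))
}

#' FEP free-energy profile along an ordered window sequence
#'
#' Free-energy change from the reference (first) window to window j:
#' gas-phase QM energy difference plus the accumulated window increments
#' of the QM/MM interaction term,
#' `dG(s_j) = [Eqm0(s_j) - Eqm0(s_R)] + sum_{i<j} g_i`,
#' with `g_i` the exponential average of the interaction-energy difference
#' between windows i+1 and i over window i's ensemble (see
#' [zwanzig_increment()]).
#'
#' When `paired_delta_e` is supplied (a list of per-transition dE sample
#' vectors, e.g. re-evaluations of neighbour geometries on the same MM
#' configurations) it is used directly and its delta-method error is the
#' window error. Otherwise the mean-shift surrogate is used: window i's
#' centred samples shifted by the difference of window means; its standard
#' error then includes, in quadrature, the block-averaged standard errors of
#' both window means, which the plain delta method cannot see.
#'
#' @param windows list of [fep_window()] objects ordered by `s`.
#' @param temperature temperature in K (default 303).
#' @param convention `"zwanzig"` (default) or `"as_printed"`.
#' @param blocks block count for error estimation (default 10).
#' @param paired_delta_e optional list (length `length(windows) - 1`) of
#'   paired dE samples per transition.
#' @return An object of class `fep_profile`: a data.frame with columns
#'   `s`, `dG`, `stderr` and attributes `temperature`, `convention`.
#' @export
fep_profile <- function(windows, temperature = 303,
                        convention = c("zwanzig", "as_printed"),
                        blocks = 10, paired_delta_e = NULL) {
  convention <- match.arg(convention)
  if (inherits(windows, "fep_window")) windows <- list(windows)
  stopifnot(all(vapply(windows, inherits, logical(1), "fep_window")))
  n <- length(windows)
  if (n == 0L) stop("no windows")
  s <- vapply(windows, `[[`, numeric(1), "s")
  if (is.unsorted(s)) stop("windows must be ordered by increasing s")
  e0 <- vapply(windows, `[[`, numeric(1), "e_qm0")
  if (n == 1L) {
    prof <- data.frame(s = s, dG = 0, stderr = 0)
  } else {
    if (!is.null(paired_delta_e) && length(paired_delta_e) != n - 1L) {
      stop_invalid("paired_delta_e", "needs one dE sample set per transition")
    }
    g <- se <- numeric(n - 1L)
    for (i in seq_len(n - 1L)) {
      if (!is.null(paired_delta_e)) {
        de <- as.numeric(paired_delta_e[[i]])
        g[i] <- zwanzig_increment(de, temperature, convention)
        se[i] <- window_error(de, temperature, blocks, convention)
      } else {
        de <- surrogate_delta_e(windows[[i]], windows[[i + 1L]])
        g[i] <- zwanzig_increment(de, temperature, convention)
        se_lme <- window_error(de, temperature, blocks, convention)
        se[i] <- sqrt(se_lme^2 +
                        block_se(windows[[i]]$samples, blocks)^2 +
                        block_se(windows[[i + 1L]]$samples, blocks)^2)
      }
    }
    prof <- data.frame(
      s = s,
      dG = (e0 - e0[1L]) + c(0, cumsum(g)),
      stderr = propagate_profile_error(se)
    )
  }
  attr(prof, "temperature") <- temperature
  attr(prof, "convention") <- convention
  class(prof) <- c("fep_profile", "data.frame")
  prof
}

# block-averaged standard error of a sample mean
block_se <- function(x, blocks = 10) {
  n <- length(x)
  if (n < 2L) return(0)
  if (n < 20L) return(stats::sd(x) / sqrt(n))
  idx <- cut(seq_len(n), breaks = blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  stats::sd(bm) / sqrt(length(bm))
}

#' Cumulative profile error from per-window errors
#'
#' Windows are treated as independent, so the error at point j is the
#' quadrature sum of the window errors accumulated from the reference.
#'
#' @param window_errors numeric vector of nonnegative per-window standard
#'   errors (kcal/mol), one per transition.
#' @return numeric vector of length `length(window_errors) + 1` of cumulative
#'   standard errors, starting at 0 for the reference point.
#' @export
propagate_profile_error <- function(window_errors) {
  window_errors <- as.numeric(window_errors)
  if (any(window_errors < 0) || any(!is.finite(window_errors))) {
    stop_invalid("window_errors", "must be finite and nonnegative")
  }
  c(0, sqrt(cumsum(window_errors^2)))
}

#' Apply harmonic vibrational corrections at stationary points
#'
#' Stationary points of a profile are corrected by the difference of their
#' vibrational free energy (or ZPE) relative to the reference point:
#' `G_corrected = dG_raw + (Gvib(point) - Gvib(reference))`. Only stationary
#' points are corrected; the reference label must be present in
#' `corrections`.
#'
#' @param profile a [fep_profile()] whose stationary points are identified by
#'   `labels`, or any data.frame with columns `s` and `dG`.
#' @param corrections named numeric vector/list, label -> vibrational free
#'   energy (kcal/mol).
#' @param labels character vector, one per profile point, `NA` for
#'   non-stationary points; the first labelled point is the reference.
#' @return data.frame with columns `label`, `s`, `dG_raw`, `correction`,
#'   `dG_corrected` over the stationary points.
#' @export
apply_stationary_corrections <- function(profile, corrections, labels) {
  corrections <- unlist(corrections)
  if (length(labels) != nrow(profile)) {
    stop_invalid("labels", "must have one entry per profile point")
  }
  idx <- which(!is.na(labels))
  if (!length(idx)) stop_invalid("labels", "no stationary points labelled")
  lab <- labels[idx]
  missing <- setdiff(lab, names(corrections))
  if (length(missing)) {
    stop("unknown label(s): no correction supplied for ",
         paste(missing, collapse = ", "))
  }
  gv <- as.numeric(corrections[lab])
  data.frame(
    label = lab,
    s = profile$s[idx],
    dG_raw = profile$dG[idx],
    correction = gv - gv[1L],
    dG_corrected = profile$dG[idx] + gv - gv[1L],
    stringsAsFactors = FALSE
  )
}

# --- window TSV I/O -----------------------------------------------------------

#' Read FEP windows from a TSV file
#'
#' Columns: `window`, `s`, `E_qm0`, then `sample_1 ... sample_n`. Lines
#' beginning with `#` are comments.
#'
#' @param file path to the TSV file.
#' @return list of [fep_window()] objects ordered by `s`.
#' @export
read_fep_windows <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  sample_cols <- grep("^sample_", names(d))
  if (!length(sample_cols)) stop("no sample_* columns in ", file)
  win <- lapply(seq_len(nrow(d)), function(i) {
    fep_window(d$window[i], d$s[i], d$E_qm0[i],
               as.numeric(d[i, sample_cols]))
  })
  win[order(vapply(win, `[[`, numeric(1), "s"))]
}

#' Write FEP windows to a TSV file
#'
#' @param windows list of [fep_window()] objects (equal sample counts).
#' @param file output path.
#' @param comment optional `#`-prefixed header comment.
#' @export
write_fep_windows <- function(windows, file, comment = NULL) {
  ns <- vapply(windows, function(w) length(w$samples), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("windows must carry equal sample counts for tabular output")
  }
  d <- data.frame(
    window = vapply(windows, `[[`, integer(1), "index"),
    s = vapply(windows, `[[`, numeric(1), "s"),
    E_qm0 = vapply(windows, `[[`, numeric(1), "e_qm0")
  )
  smp <- t(vapply(windows, `[[`, numeric(ns[1L]), "samples"))
  colnames(smp) <- paste0("sample_", seq_len(ns[1L]))
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(cbind(d, smp), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write a free-energy profile to CSV
#'
#' @param profile a [fep_profile()].
#' @param file output path.
#' @export
write_profile <- function(profile, file) {
  utils::write.csv(as.data.frame(profile)[, c("s", "dG", "stderr")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @export
print.fep_profile <- function(x, ...) {
  cat(sprintf("FEP free-energy profile: %d points, T = %g K, %s convention\n",
              nrow(x), attr(x, "temperature"), attr(x, "convention")))
  print.data.frame(x, ...)
  invisible(x)
}
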