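#' Titration series of one residue
#'
#' Protonated fraction versus pH for a titratable residue, as produced by
#' constant-pH simulation post-processing. Either per-pH fractions (with
#' optional sample counts) or raw 0/1 protonation samples can be supplied.
#'
#' @param ph numeric pH grid, strictly increasing.
#' @param fraction protonated fraction per pH, in `[0, 1]`.
#' @param counts optional per-pH sample counts behind the fractions (used as
#'   binomial weights when fitting).
#' @param residue residue identifier.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(ph, fraction, counts = NULL,
                             residue = "residue") {
  ph <- as.numeric(ph)
  fraction <- as.numeric(fraction)
  if (is.unsorted(ph, strictly = TRUE)) {
    stop_invalid("ph", "must be strictly increasing")
  }
  if (length(fraction) != length(ph) ||
      any(fraction < 0 | fraction > 1 | !is.finite(fraction))) {
    stop_invalid("fraction", "must lie in [0, 1], one per pH")
  }
  if (!is.null(counts)) {
    counts <- as.numeric(counts)
    if (length(counts) != length(ph) || any(counts < 1)) {
      stop_invalid("counts", "must be >= 1, one per pH")
    }
  }
  structure(list(residue = as.character(residue), ph = ph,
                 fraction = fraction, counts = counts),
            class = "titration_series")
}

# Hill/Henderson-Hasselbalch protonated fraction.
# base form (e.g. Lys): f = 1 / (1 + 10^(hill (pH - pKa))), decreasing in pH
hill_fraction <- function(ph, pka, hill = 1, acid = FALSE) {
  x <- if (acid) hill * (pka - ph) else hill * (ph - pka)
  1 / (1 + 10^x)
}

#' Fit a Hill titration curve
#'
#' Least-squares fit of `f(pH) = 1 / (1 + 10^(hill (pH - pKa)))` (base form;
#' `acid = TRUE` flips the sign) to a [titration_series()]. When per-pH
#' sample counts are present the fit is weighted by them (binomial
#' weighting). Standard errors come from the local curvature of the
#' least-squares surface.
#'
#' @param series a [titration_series()].
#' @param fix_hill fit with the Hill coefficient constrained to 1.
#' @param acid use the acid-form convention.
#' @return An object of class `titration_fit`: list with `pka`, `hill`,
#'   `pka_se`, `hill_se`, `residual_norm`, `acid`, `residue`.
#' @export
fit_titration <- function(series, fix_hill = FALSE, acid = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  ph <- series$ph
  f <- series$fraction
  if (length(ph) < 4L) stop("need at least 4 pH points")
  if (all(f <= 0) || all(f >= 1) || stats::sd(f) == 0) {
    stop("non-identifiable titration: fractions do not vary across the grid")
  }
  w <- if (is.null(series$counts)) rep(1, length(ph)) else series$counts
  pka0 <- ph[which.min(abs(f - 0.5))]
  d <- data.frame(ph = ph, f = f, w = w)
  if (fix_hill) {
    fit <- minpack.lm::nlsLM(f ~ hill_fraction(ph, pka, 1, acid),
                             data = d, weights = w,
                             start = list(pka = pka0))
  } else {
    fit <- minpack.lm::nlsLM(f ~ hill_fraction(ph, pka, hill, acid),
                             data = d, weights = w,
                             start = list(pka = pka0, hill = 1),
                             lower = c(pka = -Inf, hill = 1e-6))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(
    pka = unname(cf["pka"]),
    hill = if (fix_hill) 1 else unname(cf["hill"]),
    pka_se = unname(se["pka"]),
    hill_se = if (fix_hill) 0 else unname(se["hill"]),
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    acid = acid,
    residue = series$residue
  ), class = "titration_fit")
}

#' Evaluate a fitted titration curve
#'
#' @param fit a [titration_fit()][fit_titration].
#' @param ph pH value(s).
#' @return protonated fraction(s).
#' @export
predict_titration <- function(fit, ph) {
  stopifnot(inherits(fit, "titration_fit"))
  hill_fraction(ph, fit$pka, fit$hill, fit$acid)
}

#' Classify the protonation state at a working pH
#'
#' @param fit a [titration_fit()][fit_titration].
#' @param ph working pH.
#' @param thresholds length-2 numeric `c(neutral_below, protonated_above)`
#'   on the protonated fraction (default `c(0.1, 0.9)`).
#' @return list with `state` (`"protonated"`, `"neutral"` or `"mixed"`) and
#'   `fraction`.
#' @export
classify_at_ph <- function(fit, ph, thresholds = c(0.1, 0.9)) {
  frac <- predict_titration(fit, ph)
  state <- if (frac > thresholds[2L]) "protonated"
           else if (frac < thresholds[1L]) "neutral"
           else "mixed"
  list(state = state, fraction = frac)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("%s: pKa %.3f (SE %.3g), Hill %.3f (SE %.3g), %s form\n",
              x$residue, x$pka, x$pka_se, x$hill, x$hill_se,
              if (x$acid) "acid" else "base"))
  invisible(x)
}

#' Read titration data from CSV
#'
#' Long format, either `residue, pH, fraction` (optionally `count`) or raw
#' samples `residue, pH, sample, value` with 0/1 values; raw samples are
#' aggregated into per-pH fractions with counts.
#'
#' @param file path.
#' @param residue optional filter on the residue column.
#' @return a [titration_series()] (single residue) or a named list of them.
#' @export
read_titration <- function(file, residue = NULL) {
  d <- utils::read.csv(file, comment.char = "#")
  names(d) <- tolower(names(d))
  if (!is.null(residue)) d <- d[d$residue %in% residue, , drop = FALSE]
  if (!nrow(d)) stop("no rows for requested residue")
  one <- function(dd) {
    if ("fraction" %in% names(dd)) {
      dd <- dd[order(dd$ph), ]
      titration_series(dd$ph, dd$fraction,
                       counts = if ("count" %in% names(dd)) dd$count,
                       residue = dd$residue[1L])
    } else {
      agg <- stats::aggregate(value ~ ph, dd, mean)
      cnt <- stats::aggregate(value ~ ph, dd, length)
      titration_series(agg$ph, agg$value, counts = cnt$value,
                       residue = dd$residue[1L])
    }
  }
  parts <- split(d, d$residue)
  if (length(parts) == 1L) one(parts[[1L]]) else lapply(parts, one)
}
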