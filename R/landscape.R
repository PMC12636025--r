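#' One step of a multi-step reaction mechanism
#'
#' A catalytic step characterized by an activation free energy and a reaction
#' free energy. With `reference = "step_reactant"` both are measured from the
#' step's own reactant minimum (the previous step's product). With
#' `reference = "global_reference"` both are measured from the designated
#' global reference minimum — the convention used when a barrier is quoted
#' "from the most stable reactant state" rather than from the local minimum.
#'
#' @param name unique step name.
#' @param dg_act activation free energy (kcal/mol), >= 0.
#' @param dg_rxn reaction free energy (kcal/mol).
#' @param reference `"step_reactant"` (default) or `"global_reference"`.
#' @param ts_label,product_label labels for the step's transition state and
#'   product minimum; defaults derived from `name`.
#' @return An object of class `mechanism_step`.
#' @export
mechanism_step <- function(name, dg_act, dg_rxn,
                           reference = c("step_reactant", "global_reference"),
                           ts_label = paste0("TS(", name, ")"),
                           product_label = paste0("P(", name, ")")) {
  reference <- match.arg(reference)
  check_number(dg_act, "dg_act", lower = 0)
  check_number(dg_rxn, "dg_rxn")
  structure(list(name = as.character(name), dg_act = dg_act,
                 dg_rxn = dg_rxn, reference = reference,
                 ts_label = ts_label, product_label = product_label),
            class = "mechanism_step")
}

#' Assemble a stitched free-energy landscape from mechanism steps
#'
#' Stitches ordered steps into one alternating minimum/TS/minimum sequence on
#' a common energy scale: each step's reactant minimum is the previous step's
#' product minimum, and steps flagged `global_reference` place their TS and
#' product relative to the global reference minimum instead of the local
#' reactant. All energies are finally shifted so the global reference minimum
#' sits at 0.
#'
#' @param steps list of [mechanism_step()] objects in mechanistic order.
#' @param start_label label of the initial reactant minimum (default "R").
#' @param global_reference_label label of the minimum serving as global
#'   reference (default the initial minimum). It must already exist when the
#'   first `global_reference` step is stitched.
#' @return An object of class `fel_landscape`: a data.frame with columns
#'   `label`, `kind` (`"minimum"`/`"ts"`), `G` (kcal/mol).
#' @export
assemble_landscape <- function(steps, start_label = "R",
                               global_reference_label = start_label) {
  if (inherits(steps, "mechanism_step")) steps <- list(steps)
  stopifnot(length(steps) >= 1L,
            all(vapply(steps, inherits, logical(1), "mechanism_step")))
  nm <- vapply(steps, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("step names must be unique")
  label <- start_label
  kind <- "minimum"
  G <- 0
  for (st in steps) {
    if (st$reference == "global_reference") {
      i_ref <- match(global_reference_label, label)
      if (is.na(i_ref)) {
        stop("unresolvable reference: minimum '", global_reference_label,
             "' not yet defined when stitching step '", st$name, "'")
      }
      g0 <- G[i_ref]
    } else {
      g0 <- G[length(G)]               # local reactant minimum
    }
    label <- c(label, st$ts_label, st$product_label)
    kind <- c(kind, "ts", "minimum")
    G <- c(G, g0 + st$dg_act, g0 + st$dg_rxn)
  }
  i_ref <- match(global_reference_label, label)
  if (is.na(i_ref)) {
    stop("unresolvable reference: '", global_reference_label,
         "' is not a minimum of the landscape")
  }
  out <- data.frame(label = label, kind = kind, G = G - G[i_ref],
                    stringsAsFactors = FALSE)
  class(out) <- c("fel_landscape", "data.frame")
  attr(out, "reference") <- global_reference_label
  out
}

#' Construct a landscape directly from stationary points
#'
#' @param label character labels, alternating minimum/TS, starting and ending
#'   at minima.
#' @param G absolute free energies (kcal/mol) relative to the reference.
#' @param reference_label label of the reference minimum (default first).
#' @return An object of class `fel_landscape`.
#' @export
fel_landscape <- function(label, G, reference_label = label[1L]) {
  n <- length(label)
  if (n < 1L || length(G) != n) stop_invalid("G", "length mismatch")
  if (n %% 2L == 0L) stop("landscape must start and end at minima")
  kind <- rep(c("minimum", "ts"), length.out = n)
  i_ref <- match(reference_label, label[kind == "minimum"])
  if (is.na(i_ref)) stop("reference_label must name a minimum")
  out <- data.frame(label = label, kind = kind,
                    G = G - G[label == reference_label][1L],
                    stringsAsFactors = FALSE)
  class(out) <- c("fel_landscape", "data.frame")
  attr(out, "reference") <- reference_label
  out
}

#' Effective (rate-determining) barrier of a landscape
#'
#' Scans every transition state against every minimum preceding it and
#' returns the largest gap `G(TS) - min(G of preceding minima)` — the
#' effective barrier of the multi-step process — together with the achieving
#' TS and reference minimum. Ties are broken by the earliest TS.
#'
#' @param landscape a [fel_landscape()].
#' @return list with `barrier` (kcal/mol), `ts_label`, `from_label`.
#' @export
effective_barrier <- function(landscape) {
  stopifnot(inherits(landscape, "fel_landscape"))
  i_ts <- which(landscape$kind == "ts")
  if (!length(i_ts)) stop("landscape has no transition state")
  best <- NULL
  for (i in i_ts) {
    prec <- which(landscape$kind == "minimum" & seq_len(nrow(landscape)) < i)
    j <- prec[which.min(landscape$G[prec])]
    gap <- landscape$G[i] - landscape$G[j]
    if (is.null(best) || gap > best$barrier + 1e-12) {
      best <- list(barrier = gap, ts_label = landscape$label[i],
                   from_label = landscape$label[j])
    }
  }
  best
}

#' Two-state Boltzmann population fraction
#'
#' Fraction of the higher state in a two-state equilibrium separated by
#' `dG`: `exp(-dG/RT) / (1 + exp(-dG/RT))`.
#'
#' @param dg free-energy difference (kcal/mol).
#' @param temperature temperature in K.
#' @return fraction in (0, 1).
#' @export
boltzmann_fraction <- function(dg, temperature = 303) {
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  stats::plogis(-dg / kBT_kcal(temperature))
}

#' Read mechanism steps from a CSV file
#'
#' Columns: `name`, `dg_act`, `dg_rxn`, `reference` (optional; defaults to
#' `step_reactant`).
#'
#' @param file path.
#' @return list of [mechanism_step()] objects.
#' @export
read_mechanism_steps <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(d$reference)) d$reference <- "step_reactant"
  lapply(seq_len(nrow(d)), function(i) {
    mechanism_step(d$name[i], d$dg_act[i], d$dg_rxn[i], d$reference[i])
  })
}

#' @export
print.fel_landscape <- function(x, ...) {
  cat("Free-energy landscape (kcal/mol, reference =",
      attr(x, "reference"), "):\n")
  gmin <- min(x$G)
  span <- max(x$G) - gmin
  width <- 40L
  for (i in seq_len(nrow(x))) {
    pos <- if (span > 0) round((x$G[i] - gmin) / span * width) else 0L
    cat(sprintf("%10s %s %s%s %7.2f\n", x$label[i],
                if (x$kind[i] == "ts") "ts " else "min",
                strrep(" ", pos), "*", x$G[i]))
  }
  eb <- effective_barrier(x)
  cat(sprintf("effective barrier: %.2f kcal/mol at %s (from %s)\n",
              eb$barrier, eb$ts_label, eb$from_label))
  invisible(x)
}
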