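#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected;
#' every numeric field is range-checked and reported by name. The resolved
#' configuration (defaults included) is written alongside every run so a
#' run can be reproduced bit-for-bit from its own output.
#'
#' @param stages character subset of
#'   `c("fep", "landscape", "tst", "titration", "progress", "trajectory")`.
#' @param temperature temperature in K.
#' @param convention FEP sign convention, `"zwanzig"` or `"as_printed"`.
#' @param blocks block count for FEP error estimation.
#' @param tof_window_h initial-rate window (h), `NA` = through 3rd point.
#' @param titration_thresholds length-2 protonation thresholds.
#' @param unbind_threshold,unbind_persistence unbinding detection settings.
#' @param seed integer seed for the synthetic generators.
#' @param out_dir output directory.
#' @param steps_file optional CSV of mechanism steps (see
#'   [read_mechanism_steps()]); `NULL` uses the built-in four-step
#'   urethanase demo landscape.
#' @param rates named list of `list(k, temperature)` rate measurements for
#'   the TST stage.
#' @param ... reserved; supplying unknown keys is an error.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("fep", "landscape", "tst",
                                       "titration", "progress",
                                       "trajectory"),
                            temperature = 303,
                            convention = "zwanzig",
                            blocks = 10,
                            tof_window_h = NA,
                            titration_thresholds = c(0.1, 0.9),
                            unbind_threshold = 10,
                            unbind_persistence = 50,
                            seed = 1,
                            out_dir = tempfile("fepland_run_"),
                            steps_file = NULL,
                            rates = list(
                              tof = list(k = 1.77e-4, temperature = 303),
                              decarboxylation = list(k = 49,
                                                     temperature = 298.15)),
                            ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  }
  known <- c("fep", "landscape", "tst", "titration", "progress",
             "trajectory")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop_invalid("stages", paste("unknown stage(s):",
                                 paste(bad, collapse = ", ")))
  }
  check_number(temperature, "temperature", lower = 0,
               allow_equal_lower = FALSE)
  convention <- match.arg(convention, c("zwanzig", "as_printed"))
  blocks <- check_count(blocks, "blocks", min = 2L)
  if (!is.na(tof_window_h)) check_number(tof_window_h, "tof_window_h",
                                         lower = 0,
                                         allow_equal_lower = FALSE)
  if (length(titration_thresholds) != 2L ||
      any(titration_thresholds < 0 | titration_thresholds > 1) ||
      titration_thresholds[1] >= titration_thresholds[2]) {
    stop_invalid("titration_thresholds", "need 0 <= low < high <= 1")
  }
  check_number(unbind_threshold, "unbind_threshold", lower = 0)
  unbind_persistence <- check_count(unbind_persistence,
                                    "unbind_persistence", min = 1L)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.null(steps_file) && !nzchar(steps_file)) steps_file <- NULL
  structure(list(stages = stages, temperature = temperature,
                 convention = convention, blocks = blocks,
                 tof_window_h = tof_window_h,
                 titration_thresholds = titration_thresholds,
                 unbind_threshold = unbind_threshold,
                 unbind_persistence = unbind_persistence,
                 seed = seed, out_dir = out_dir, steps_file = steps_file,
                 rates = rates),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param file YAML path; keys as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  do.call(pipeline_config, vals)
}

# built-in demo landscape: the four-step urethanase mechanism
default_mechanism_steps <- function() {
  list(
    mechanism_step("conformational", 4.5, 2.6,
                   ts_label = "TSconf", product_label = "ES_active"),
    mechanism_step("acylation", 21.2, -16.7, reference = "global_reference",
                   ts_label = "TS1(A)", product_label = "EA"),
    mechanism_step("hydrolysis", 18.2, -11.1,
                   ts_label = "TS(H)", product_label = "PC(H)"),
    mechanism_step("decarboxylation", 12.1, 9.1,
                   ts_label = "TS(D)", product_label = "PC(D)")
  )
}

#' Run the analysis pipeline end to end on synthetic inputs
#'
#' Executes the requested stages — synthetic FEP generation + profile
#' estimation + truth comparison, landscape assembly + effective barrier,
#' TST rate/barrier interconversion, titration generation + fit, progress
#' curve generation + TOF/TTN, trajectory generation + unbinding detection —
#' and writes CSV/JSON reports plus the resolved configuration and a run
#' log into `config$out_dir`.
#'
#' @param config a [pipeline_config()] or a YAML path.
#' @return Invisibly, the report bundle (named list per stage).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed)

  if ("fep" %in% config$stages) {
    gen <- generate_fep_windows(synthetic_fep_spec(
      temperature = config$temperature, seed = config$seed))
    prof <- fep_profile(gen$windows, temperature = config$temperature,
                        convention = config$convention,
                        blocks = config$blocks)
    dev <- prof$dG - gen$truth$G
    report$fep <- list(
      profile = as.data.frame(prof),
      truth = gen$truth$G,
      max_abs_deviation = max(abs(dev)),
      frac_within_3se = mean(abs(dev[-1L]) < 3 * prof$stderr[-1L])
    )
    write_profile(prof, file.path(config$out_dir, "fep_profile.csv"))
  }

  if ("landscape" %in% config$stages) {
    steps <- if (is.null(config$steps_file)) default_mechanism_steps()
             else read_mechanism_steps(config$steps_file)
    ls <- assemble_landscape(steps, start_label = "ES",
                             global_reference_label = "ES")
    eb <- effective_barrier(ls)
    report$landscape <- list(landscape = as.data.frame(ls),
                             effective_barrier = eb)
    utils::write.csv(as.data.frame(ls),
                     file.path(config$out_dir, "landscape.csv"),
                     row.names = FALSE)
    report$landscape$rate_s <- rate_from_barrier(eb$barrier,
                                                 config$temperature)
  }

  if ("tst" %in% config$stages) {
    report$tst <- lapply(config$rates, function(r) {
      list(k = r$k, temperature = r$temperature,
           barrier_kcal = barrier_from_rate(r$k, r$temperature))
    })
  }

  if ("titration" %in% config$stages) {
    gen <- generate_titration(synthetic_titration_spec(seed = config$seed))
    fit <- fit_titration(gen$series)
    cls <- classify_at_ph(fit, 8, config$titration_thresholds)
    report$titration <- list(pka = fit$pka, hill = fit$hill,
                             pka_true = gen$truth$pka,
                             state_at_ph8 = cls$state,
                             fraction_at_ph8 = cls$fraction)
  }

  if ("progress" %in% config$stages) {
    gen <- generate_progress(synthetic_progress_spec(seed = config$seed))
    win <- if (is.na(config$tof_window_h)) NULL else config$tof_window_h
    ks <- tof_ttn(gen$curve, initial_window = win)
    report$progress <- list(tof_s = ks$tof_s, ttn = ks$ttn,
                            plateau_uM = ks$plateau_uM,
                            truth_tof_s = gen$truth$tof_s,
                            truth_plateau = gen$truth$plateau)
  }

  if ("trajectory" %in% config$stages) {
    gen <- generate_trajectory(synthetic_trajectory_spec(
      unbind_frame = 400, seed = config$seed))
    ds <- distance_series(gen$traj, "OG", "C1")
    report$trajectory <- list(
      unbind_frame = detect_unbinding(ds, config$unbind_threshold,
                                      config$unbind_persistence),
      truth_unbind_frame = gen$truth$unbind_frame,
      mode_distance = ds$mode)
  }

  resolved <- unclass(config)
  resolved$steps_file <- resolved$steps_file %||% ""
  yaml::write_yaml(resolved, file.path(config$out_dir, "config.yaml"))
  jsonlite::write_json(
    report_for_json(report),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("fepland %s", as.character(utils::packageVersion("fepland"))),
    sprintf("seed: %d", config$seed),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    sprintf("R: %s", R.version.string)
  ), file.path(config$out_dir, "run_log.txt"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# drop data frames down to plain lists for JSON serialization
report_for_json <- function(x) {
  if (is.data.frame(x)) return(as.list(x))
  if (is.list(x)) return(lapply(x, report_for_json))
  x
}
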