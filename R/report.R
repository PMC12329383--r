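#' Analysis configuration for the reporting pipeline
#'
#' Collects every constant the end-to-end analysis uses, so a whole run
#' is reproducible from one object (or one YAML/JSON file via
#' [read_analysis_config()]).
#'
#' @param n_resamples,scheme,alpha,intervention_phases randomization-test
#'   settings (see [randomization_p()] and [randomization_table()]).
#' @param randomization_measures measures entering the randomization
#'   table.
#' @param contrast_measures measures entering the timepoint contrasts.
#' @param reliability named list of [reliability_params()].
#' @param vr a [vr_effect_config()].
#' @param seed integer seed for the run.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(n_resamples = 1000,
                            scheme = "label_permutation",
                            alpha = 0.05,
                            intervention_phases = c("B", "B2"),
                            randomization_measures = c("ECBI_INTENSITY",
                                                       "OBVL_K"),
                            contrast_measures = c("DPICS_PF", "DPICS_NL"),
                            reliability = default_reliability_params(),
                            vr = vr_effect_config(),
                            seed = NULL) {
  structure(list(n_resamples = n_resamples, scheme = scheme, alpha = alpha,
                 intervention_phases = intervention_phases,
                 randomization_measures = randomization_measures,
                 contrast_measures = contrast_measures,
                 reliability = reliability, vr = vr, seed = seed),
            class = "analysis_config")
}

#' Read an analysis/simulation configuration from YAML or JSON
#'
#' Scalar fields override the defaults of [analysis_config()] /
#' [simulation_config()]; unknown keys are an error. Reliability and VR
#' sub-configurations may be given as nested maps.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @param type `"analysis"` or `"simulation"`.
#' @return an `analysis_config` or `simulation_config`.
#' @export
read_analysis_config <- function(path, type = c("analysis", "simulation")) {
  type <- match.arg(type)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  build <- if (type == "analysis") analysis_config else simulation_config
  fml <- names(formals(build))
  unknown <- setdiff(names(raw), c(fml, "reliability", "vr"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (type == "analysis" && !is.null(raw$reliability)) {
    raw$reliability <- lapply(stats::setNames(names(raw$reliability),
                                              names(raw$reliability)),
      function(ms) do.call(reliability_params,
                           c(list(measure = ms), raw$reliability[[ms]])))
  }
  if (type == "analysis" && !is.null(raw$vr)) {
    raw$vr <- do.call(vr_effect_config, raw$vr)
  }
  if (type == "simulation") {
    for (nm in c("baseline_mean", "within_sd", "effect_b", "effect_b2",
                 "slope")) {
      if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
    }
  }
  do.call(build, raw)
}

#' Run the full analysis of a study dataset
#'
#' Produces the five report tables in one pass: the per-participant
#' randomization tests with group p-value combination, the VR
#' session-difference table, the pre/post/follow-up contrasts, the
#' raw-score table with clinical-range marks and VR-use grouping, and the
#' reliable-change table. Every cell is the direct output of the
#' corresponding analysis function; the report layer re-derives nothing.
#'
#' @param dataset a [study_dataset()].
#' @param config an [analysis_config()].
#' @return an `analysis_report`: list of `randomization`, `vr_effect`,
#'   `contrasts` (list of descriptives + contrasts), `raw_scores`,
#'   `rci`, and `meta` (seed, settings hash, package version, counts of
#'   excluded participants).
#' @export
analyze_study <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "study_dataset"),
            inherits(config, "analysis_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (!nrow(dataset$participants)) {
    stop("no analyzable participants in dataset", call. = FALSE)
  }
  randomization <- randomization_table(
    dataset, measures = config$randomization_measures,
    intervention_phases = config$intervention_phases,
    n_resamples = config$n_resamples, scheme = config$scheme)
  excluded <- attr(randomization, "excluded")
  if (!is.null(excluded) && nrow(excluded)) {
    message("randomization table: excluded ", nrow(excluded),
            " participant-measure series (",
            paste(unique(excluded$participant_id), collapse = ", "), ")")
  }
  vr_effect <- vr_effect_table(dataset, config$vr)
  contrasts <- contrast_table(dataset, config$contrast_measures)
  raw_scores <- raw_score_table(dataset, config)
  rci_tab <- rci_table(dataset, config$reliability)
  structure(list(
    randomization = randomization,
    vr_effect = vr_effect,
    contrasts = contrasts,
    raw_scores = raw_scores,
    rci = rci_tab,
    meta = list(
      seed = if (is.null(config$seed)) NA_integer_ else config$seed,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("mbsced")),
      n_participants = nrow(dataset$participants),
      n_excluded_series = if (is.null(excluded)) 0L else nrow(excluded))),
    class = "analysis_report")
}

#' Raw assessment scores with clinical marks and VR grouping
#'
#' Per participant and measure, the T0/T1/T2 assessment values, their
#' clinical-range status (where a cutoff is configured), the total VR
#' practice count and the low/high VR-use group.
#'
#' @param dataset a [study_dataset()].
#' @param config an [analysis_config()].
#' @return tibble with columns `participant_id`, `vr_total`, `vr_group`,
#'   `measure`, `timepoint`, `value`, `clinical`.
#' @export
raw_score_table <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "study_dataset"))
  obs <- dataset$observations
  obs <- obs[obs$phase %in% assessment_phases(), ]
  if (!nrow(obs)) {
    return(tibble::tibble(participant_id = character(), vr_total = double(),
                          vr_group = character(), measure = character(),
                          timepoint = character(), value = double(),
                          clinical = character()))
  }
  totals <- vr_totals(dataset)
  groups <- split_by_use(totals, config$vr$group_split_cutoff)
  out <- tibble::tibble(
    participant_id = obs$participant_id,
    measure = obs$measure, timepoint = obs$phase, value = obs$value)
  out$vr_total <- groups$total[match(out$participant_id,
                                     groups$participant_id)]
  out$vr_group <- groups$vr_group[match(out$participant_id,
                                        groups$participant_id)]
  out$clinical <- NA_character_
  for (ms in names(config$reliability)) {
    pp <- config$reliability[[ms]]
    if (is.na(pp$clinical_cutoff)) next
    sel <- out$measure == ms
    out$clinical[sel] <- clinical_status(out$value[sel], pp)
  }
  out[, c("participant_id", "vr_total", "vr_group", "measure", "timepoint",
          "value", "clinical")]
}

#' Plot-data export for visual inspection
#'
#' Visual inspection of annotated series plots is the first analysis of
#' any single-case design. This export fully specifies those plots as
#' data: each participant x measure series with week indices and phase
#' labels, the phase-boundary marker weeks (A|B, B|B2, B2|C), the VR
#' add-on start week, and for the DPICS composites the reference bands
#' used to judge skill levels (positive following above 30 is considered
#' good, negative leading below 5 is considered good). Plotting itself is
#' left to downstream tooling.
#'
#' @param dataset a [study_dataset()] with design assignments.
#' @param n_intervention_weeks,followup_gap_weeks schedule constants used
#'   to materialize phase boundaries when a design row is present.
#' @return tibble with one row per participant x measure: list-columns
#'   `series` (week/phase/value tibble) and `markers` (named list of
#'   boundary weeks, `NULL` entries omitted), plus `band` (reference
#'   threshold, `NA` for non-DPICS measures) and `band_side`
#'   (`"above"`/`"below"`).
#' @export
plot_data <- function(dataset, n_intervention_weeks = NULL,
                      followup_gap_weeks = 26) {
  stopifnot(inherits(dataset, "study_dataset"))
  obs <- dataset$observations
  weekly <- obs[obs$phase %in% weekly_phases(), ]
  rows <- list()
  for (pid in unique(weekly$participant_id)) {
    pobs <- weekly[weekly$participant_id == pid, ]
    markers <- series_markers(pobs)
    drow <- dataset$design[dataset$design$participant_id == pid, ]
    if (nrow(drow) == 1) {
      markers$addon_start_week <- drow$baseline_length + drow$addon_start
    }
    for (ms in unique(pobs$measure)) {
      s <- pobs[pobs$measure == ms, c("week_index", "phase", "value")]
      s <- s[order(s$week_index), ]
      mk <- markers
      if (!"B2" %in% s$phase) mk$addon_start_week <- NULL
      band <- switch(ms, DPICS_PF = 30, DPICS_NL = 5, NA_real_)
      band_side <- switch(ms, DPICS_PF = "above", DPICS_NL = "below",
                          NA_character_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, measure = ms,
        series = list(s), markers = list(mk),
        band = band, band_side = band_side)
    }
  }
  dplyr::bind_rows(rows)
}

# first week of each later phase, from the observed phase labels
series_markers <- function(pobs) {
  mk <- list()
  for (ph in c("B", "B2", "C")) {
    w <- pobs$week_index[pobs$phase == ph]
    if (length(w)) mk[[paste0(ph, "_start_week")]] <- min(w)
  }
  mk
}

#' Write an analysis report to disk
#'
#' Emits each table as CSV plus one JSON bundle holding every table and
#' the run metadata.
#'
#' @param report an [analyze_study()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, nm) {
    utils::write.csv(x, file.path(out_dir, nm), row.names = FALSE, na = "")
  }
  wcsv(report$randomization, "randomization_tests.csv")
  wcsv(report$vr_effect, "vr_session_diffs.csv")
  wcsv(report$contrasts$descriptives, "timepoint_descriptives.csv")
  wcsv(report$contrasts$contrasts, "timepoint_contrasts.csv")
  wcsv(report$raw_scores, "raw_scores.csv")
  wcsv(report$rci, "reliable_change.csv")
  excl <- attr(report$randomization, "excluded")
  if (!is.null(excl) && nrow(excl)) wcsv(excl, "randomization_exclusions.csv")
  jsonlite::write_json(
    list(randomization = report$randomization,
         vr_effect = report$vr_effect,
         timepoint_descriptives = report$contrasts$descriptives,
         timepoint_contrasts = report$contrasts$contrasts,
         raw_scores = report$raw_scores,
         rci = report$rci,
         rci_summary = attr(report$rci, "summary"),
         meta = report$meta),
    file.path(out_dir, "report.json"),
    dataframe = "rows", na = "null", digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}

#' Pipeline entry points: simulate, analyze, export plot data
#'
#' Thin file-level wrappers over the analysis functions, used by the
#' command-line script shipped in `inst/cli/`. `run_simulate()` writes
#' `observations.csv`, `sessions.csv`, `design.csv` and
#' `participants.csv`; `run_analyze()` reads them back, runs
#' [analyze_study()] and writes the report; `run_plotdata()` writes one
#' JSON series file per participant x measure with markers and reference
#' bands.
#'
#' @param config a [simulation_config()] / [analysis_config()] or a path
#'   to a YAML/JSON file encoding one.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param data_dir directory holding the dataset files written by
#'   [run_simulate()].
#' @return the output directory, invisibly (the dataset, for
#'   `load_dataset_dir()`).
#' @export
run_simulate <- function(config = simulation_config(), out_dir, seed = NULL) {
  if (is.character(config)) {
    config <- read_analysis_config(config, "simulation")
  }
  ds <- simulate_dataset(config, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_long_csv(ds, file.path(out_dir, "observations.csv"))
  write_sessions_csv(ds$sessions, file.path(out_dir, "sessions.csv"))
  write_design_csv(ds$design, file.path(out_dir, "design.csv"))
  utils::write.csv(ds$participants, file.path(out_dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = if (is.null(seed)) NA_integer_ else seed,
         config_hash = rlang::hash(config)),
    file.path(out_dir, "run_meta.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @export
load_dataset_dir <- function(data_dir) {
  parts <- utils::read.csv(file.path(data_dir, "participants.csv"),
                           colClasses = "character")
  sess_path <- file.path(data_dir, "sessions.csv")
  des_path <- file.path(data_dir, "design.csv")
  read_long_csv(file.path(data_dir, "observations.csv"),
                participants = parts,
                sessions = if (file.exists(sess_path))
                  read_sessions_csv(sess_path),
                design = if (file.exists(des_path))
                  read_design_csv(des_path))
}

#' @rdname run_simulate
#' @export
run_analyze <- function(data_dir, config = analysis_config(), out_dir) {
  if (is.character(config)) {
    config <- read_analysis_config(config, "analysis")
  }
  ds <- load_dataset_dir(data_dir)
  report <- analyze_study(ds, config)
  write_report(report, out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @export
run_plotdata <- function(data_dir, out_dir, followup_gap_weeks = 26) {
  ds <- if (inherits(data_dir, "study_dataset")) data_dir else
    load_dataset_dir(data_dir)
  pd <- plot_data(ds, followup_gap_weeks = followup_gap_weeks)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(pd))) {
    fn <- sprintf("%s_%s.json", pd$participant_id[i], pd$measure[i])
    payload <- list(participant_id = pd$participant_id[i],
                    measure = pd$measure[i],
                    series = pd$series[[i]],
                    markers = pd$markers[[i]])
    if (!is.na(pd$band[i])) {
      payload$band <- list(threshold = pd$band[i], side = pd$band_side[i])
    }
    jsonlite::write_json(payload, file.path(out_dir, fn),
                         dataframe = "rows", na = "null", digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(out_dir)
}
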