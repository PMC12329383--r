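#' Assemble and validate a SCED study dataset
#'
#' A `study_dataset` bundles everything one multiple-baseline study
#' produces: the long table of weekly and assessment scores, per-participant
#' metadata (dropout status), per-session DPICS tallies with VR practice
#' counts, and the design assignments (baseline length, add-on start).
#'
#' @param observations data frame with columns `participant_id`, `measure`,
#'   `week_index`, `phase`, `value`. `value` may be `NA` (a missed
#'   measurement). `week_index` is 0-based from the first baseline week and
#'   must be a non-negative integer for weekly phases; assessment rows
#'   (`T0`/`T1`/`T2`) may leave it `NA`.
#' @param participants optional data frame with columns `participant_id`
#'   and `dropout_status` (one of `"completer"`, `"dropped_intervention"`,
#'   `"dropped_fully"`). Participants present in `observations`, `sessions`
#'   or `design` but absent here are added as completers.
#' @param sessions optional data frame of per-session DPICS tallies:
#'   `participant_id`, `session_index`, the eight DPICS category columns
#'   (see [dpics_tally()]), and `vr_practices_since_previous`.
#' @param design optional data frame of design assignments:
#'   `participant_id`, `baseline_length`, `addon_start`, `rng_seed`.
#' @param ranges measure range table, by default [sced_measures()].
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `participants`, `observations`, `sessions`, `design`, all tibbles.
#' @seealso [read_long_csv()], [write_long_csv()], [extract_phase()]
#' @export
study_dataset <- function(observations = NULL, participants = NULL,
                          sessions = NULL, design = NULL,
                          ranges = sced_measures()) {
  observations <- normalize_observations(observations)
  sessions <- normalize_sessions(sessions)
  design <- normalize_design(design)

  ids <- unique(c(observations$participant_id, sessions$participant_id,
                  design$participant_id,
                  if (!is.null(participants)) as.character(participants$participant_id)))
  if (is.null(participants)) {
    participants <- tibble::tibble(participant_id = character(),
                                   dropout_status = character())
  } else {
    participants <- tibble::tibble(
      participant_id = as.character(participants$participant_id),
      dropout_status = if ("dropout_status" %in% names(participants))
        as.character(participants$dropout_status) else "completer"
    )
  }
  missing_ids <- setdiff(ids, participants$participant_id)
  if (length(missing_ids)) {
    participants <- dplyr::bind_rows(
      participants,
      tibble::tibble(participant_id = missing_ids, dropout_status = "completer")
    )
  }
  participants <- dplyr::arrange(participants, .data$participant_id)

  ds <- structure(
    list(participants = participants, observations = observations,
         sessions = sessions, design = design),
    class = "study_dataset"
  )
  validate_dataset(ds, ranges = ranges)
  ds
}

normalize_observations <- function(observations) {
  if (is.null(observations)) {
    return(tibble::tibble(participant_id = character(), measure = character(),
                          week_index = integer(), phase = character(),
                          value = double()))
  }
  req <- c("participant_id", "measure", "week_index", "phase", "value")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("observations is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    participant_id = as.character(observations$participant_id),
    measure = as.character(observations$measure),
    week_index = suppressWarnings(as.integer(observations$week_index)),
    phase = as.character(observations$phase),
    value = suppressWarnings(as.numeric(observations$value))
  )
  dplyr::arrange(out, .data$participant_id, .data$measure, .data$week_index,
                 .data$phase)
}

normalize_sessions <- function(sessions) {
  cats <- dpics_categories()
  if (is.null(sessions)) {
    out <- tibble::tibble(participant_id = character(), session_index = integer())
    for (cc in cats) out[[cc]] <- integer()
    out$vr_practices_since_previous <- integer()
    return(out)
  }
  req <- c("participant_id", "session_index", cats)
  missing_cols <- setdiff(req, names(sessions))
  if (length(missing_cols)) {
    stop("sessions is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(sessions)
  out$participant_id <- as.character(out$participant_id)
  out$session_index <- as.integer(out$session_index)
  if (!"vr_practices_since_previous" %in% names(out)) {
    out$vr_practices_since_previous <- 0L
  }
  out$vr_practices_since_previous <- as.integer(out$vr_practices_since_previous)
  dplyr::arrange(out, .data$participant_id, .data$session_index)
}

normalize_design <- function(design) {
  if (is.null(design)) {
    return(tibble::tibble(participant_id = character(),
                          baseline_length = integer(), addon_start = integer(),
                          rng_seed = integer()))
  }
  req <- c("participant_id", "baseline_length", "addon_start")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    participant_id = as.character(design$participant_id),
    baseline_length = as.integer(design$baseline_length),
    addon_start = as.integer(design$addon_start),
    rng_seed = if ("rng_seed" %in% names(design))
      as.integer(design$rng_seed) else NA_integer_
  )
}

#' Validate a study dataset
#'
#' Checks the structural invariants of a [study_dataset()]: known measure
#' and phase tokens, in-range values (e.g. ECBI Intensity within 36-252,
#' ECBI Problem within 0-36), integer constraints for count measures,
#' non-negative week indices, no duplicated
#' (participant, measure, week, phase) cells, unique participant ids, and
#' referential integrity of sessions and design rows. Called by
#' [study_dataset()] and [read_long_csv()]; exported so externally built
#' objects can be re-checked.
#'
#' @param dataset a `study_dataset`.
#' @param ranges measure range table, by default [sced_measures()].
#' @return `dataset`, invisibly. Errors describe the first offending rows.
#' @export
validate_dataset <- function(dataset, ranges = sced_measures()) {
  stopifnot(inherits(dataset, "study_dataset"))
  obs <- dataset$observations

  bad <- which(!obs$measure %in% ranges$measure)
  if (length(bad)) {
    stop("unknown measure token '", obs$measure[bad[1]], "' (observation row ",
         bad[1], ")", call. = FALSE)
  }
  bad <- which(!obs$phase %in% sced_phases())
  if (length(bad)) {
    stop("unknown phase token '", obs$phase[bad[1]], "' (observation row ",
         bad[1], ")", call. = FALSE)
  }
  weekly <- obs$phase %in% weekly_phases()
  bad <- which(weekly & is.na(obs$week_index))
  if (length(bad)) {
    stop("weekly observation without week_index (row ", bad[1], ")",
         call. = FALSE)
  }
  bad <- which(!is.na(obs$week_index) & obs$week_index < 0)
  if (length(bad)) {
    stop("negative week_index (observation row ", bad[1], ")", call. = FALSE)
  }

  idx <- match(obs$measure, ranges$measure)
  v <- obs$value
  present <- !is.na(v)
  bad <- which(present & (v < ranges$min[idx] | v > ranges$max[idx]))
  if (length(bad)) {
    stop("value ", v[bad[1]], " outside the admissible range [",
         ranges$min[idx[bad[1]]], ", ", ranges$max[idx[bad[1]]], "] for ",
         obs$measure[bad[1]], " (observation row ", bad[1], ")", call. = FALSE)
  }
  bad <- which(present & ranges$integer[idx] & v != round(v))
  if (length(bad)) {
    stop("non-integer value ", v[bad[1]], " for count measure ",
         obs$measure[bad[1]], " (observation row ", bad[1], ")", call. = FALSE)
  }

  key <- paste(obs$participant_id, obs$measure, obs$week_index, obs$phase,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate observation for (participant, measure, week, phase) = (",
         gsub("\r", ", ", d), ")", call. = FALSE)
  }

  if (anyDuplicated(dataset$participants$participant_id)) {
    stop("duplicate participant ids in participants table", call. = FALSE)
  }
  bad_status <- setdiff(dataset$participants$dropout_status, dropout_levels())
  if (length(bad_status)) {
    stop("unknown dropout_status '", bad_status[1], "'", call. = FALSE)
  }

  known <- dataset$participants$participant_id
  orphan <- setdiff(dataset$sessions$participant_id, known)
  if (length(orphan)) {
    stop("session record references unknown participant '", orphan[1], "'",
         call. = FALSE)
  }
  orphan <- setdiff(dataset$design$participant_id, known)
  if (length(orphan)) {
    stop("design assignment references unknown participant '", orphan[1], "'",
         call. = FALSE)
  }
  if (nrow(dataset$sessions)) {
    cats <- dpics_categories()
    m <- as.matrix(dataset$sessions[, cats])
    if (any(!is.na(m) & (m < 0 | m != round(m)))) {
      stop("DPICS tallies must be non-negative integers", call. = FALSE)
    }
    ses <- dplyr::group_by(dataset$sessions, .data$participant_id)
    dup <- dplyr::summarise(ses, dup = anyDuplicated(.data$session_index) > 0)
    if (any(dup$dup)) {
      stop("session_index must be strictly increasing per participant",
           call. = FALSE)
    }
    if (any(dataset$sessions$vr_practices_since_previous < 0, na.rm = TRUE)) {
      stop("vr_practices_since_previous must be non-negative", call. = FALSE)
    }
  }
  if (nrow(dataset$design)) {
    if (!all(dataset$design$baseline_length %in% c(4L, 5L, 6L))) {
      stop("baseline_length must be 4, 5 or 6 weeks", call. = FALSE)
    }
    if (!all(dataset$design$addon_start %in% c(0L, 3L, 6L))) {
      stop("addon_start must be 0, 3 or 6 sessions", call. = FALSE)
    }
  }
  invisible(dataset)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  cat("  participants:", nrow(x$participants), "\n")
  cat("  observations:", nrow(x$observations), "across",
      length(unique(x$observations$measure)), "measure(s)\n")
  cat("  session records:", nrow(x$sessions), "\n")
  cat("  design assignments:", nrow(x$design), "\n")
  invisible(x)
}

#' Read and write the long-format observation CSV
#'
#' The interchange format is a single comma-delimited, UTF-8, headered
#' file with columns `participant_id`, `measure`, `week_index`, `phase`,
#' `value`. Blank `value` fields are missing measurements, never zero.
#' `write_long_csv()` emits rows in the deterministic
#' (participant, measure, week, phase) order and writes missing values as
#' empty fields, so read-write-read is the identity on valid datasets.
#'
#' @param path file path.
#' @param participants,sessions,design optional companion tables passed on
#'   to [study_dataset()] (the observation CSV itself carries neither
#'   dropout status nor session records; see [write_dataset_json()] for a
#'   single-file lossless export).
#' @param ranges measure range table used for validation.
#' @return `read_long_csv()` a validated `study_dataset`;
#'   `write_long_csv()` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' ds <- study_dataset(data.frame(
#'   participant_id = "P09", measure = "ECBI_INTENSITY",
#'   week_index = 3, phase = "A", value = 151
#' ))
#' write_long_csv(ds, f)
#' read_long_csv(f)
#' @export
read_long_csv <- function(path, participants = NULL, sessions = NULL,
                          design = NULL, ranges = sced_measures()) {
  raw <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                         check.names = FALSE)
  req <- c("participant_id", "measure", "week_index", "phase", "value")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("'", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::tibble(
    participant_id = raw$participant_id,
    measure = raw$measure,
    week_index = parse_int_field(raw$week_index, path, "week_index"),
    phase = raw$phase,
    value = parse_num_field(raw$value, path, "value")
  )
  study_dataset(obs, participants = participants, sessions = sessions,
                design = design, ranges = ranges)
}

parse_int_field <- function(x, path, field) {
  x <- trimws(x)
  out <- rep(NA_integer_, length(x))
  nonblank <- !is.na(x) & nzchar(x)
  conv <- suppressWarnings(as.integer(x[nonblank]))
  bad <- which(is.na(conv))
  if (length(bad)) {
    stop("'", path, "': cannot parse ", field, " '",
         x[nonblank][bad[1]], "' (data row ", which(nonblank)[bad[1]], ")",
         call. = FALSE)
  }
  out[nonblank] <- conv
  out
}

parse_num_field <- function(x, path, field) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  nonblank <- !is.na(x) & nzchar(x)
  conv <- suppressWarnings(as.numeric(x[nonblank]))
  bad <- which(is.na(conv))
  if (length(bad)) {
    stop("'", path, "': cannot parse ", field, " '",
         x[nonblank][bad[1]], "' (data row ", which(nonblank)[bad[1]], ")",
         call. = FALSE)
  }
  out[nonblank] <- conv
  out
}

#' @rdname read_long_csv
#' @param dataset a `study_dataset`.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  obs <- dplyr::arrange(dataset$observations, .data$participant_id,
                        .data$measure, .data$week_index, .data$phase)
  utils::write.csv(obs, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Lossless JSON export of a study dataset
#'
#' Serializes all four component tables (participants, observations,
#' sessions, design) so that, unlike the observation-only CSV,
#' `read_dataset_json(write_dataset_json(ds))` restores the full object.
#'
#' @param dataset a `study_dataset`.
#' @param path file path.
#' @return the path / the restored `study_dataset`.
#' @export
write_dataset_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  jsonlite::write_json(
    list(participants = dataset$participants,
         observations = dataset$observations,
         sessions = dataset$sessions,
         design = dataset$design),
    path, dataframe = "columns", na = "null", digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_dataset_json
#' @export
read_dataset_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(el, proto) {
    if (is.null(el) || length(el) == 0) return(NULL)
    tibble::as_tibble(el)
  }
  study_dataset(observations = as_tbl(x$observations),
                participants = as_tbl(x$participants),
                sessions = as_tbl(x$sessions),
                design = as_tbl(x$design))
}

#' Extract one participant's phase values in week order
#'
#' Returns the non-missing values of one measure whose phase label falls in
#' `phases`, ordered by `week_index`. This is the selection step feeding
#' the randomization test, which requires at least 2 measurement points in
#' the baseline and in the intervention phases.
#'
#' @param dataset a `study_dataset`.
#' @param participant_id participant label.
#' @param measure measure token (see [sced_measures()]).
#' @param phases character vector of phase tokens to keep.
#' @return numeric vector (possibly empty), ordered by week; assessment
#'   rows (no week index) come first in phase-label order if requested.
#' @export
extract_phase <- function(dataset, participant_id, measure,
                          phases = c("A")) {
  stopifnot(inherits(dataset, "study_dataset"))
  bad <- setdiff(phases, sced_phases())
  if (length(bad)) stop("unknown phase token '", bad[1], "'", call. = FALSE)
  if (!measure %in% sced_measures()$measure) {
    stop("unknown measure token '", measure, "'", call. = FALSE)
  }
  obs <- dataset$observations
  keep <- obs$participant_id == participant_id & obs$measure == measure &
    obs$phase %in% phases & !is.na(obs$value)
  obs <- obs[keep, ]
  obs <- obs[order(obs$week_index, match(obs$phase, sced_phases())), ]
  obs$value
}
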