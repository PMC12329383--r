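#' Randomize the multiple-baseline design
#'
#' Each participant in the study receives two independent randomizations
#' at entry: a baseline length of 4, 5 or 6 weekly measurements (phase A)
#' and a staggered add-on start -- the VR practice tool is introduced
#' straight away, after 3 sessions, or after 6 sessions. Both draws are
#' uniform over their three options and drawn independently per
#' participant, giving a uniform 3 x 3 cell distribution. The staggering of
#' baselines across participants is what lets a nonconcurrent
#' multiple-baseline design separate intervention effects from time
#' effects.
#'
#' @param participant_ids non-empty character vector of unique ids.
#' @param seed optional integer; if supplied, draws are reproducible.
#' @return tibble with columns `participant_id`, `baseline_length`
#'   (weeks, in \{4,5,6\}), `addon_start` (sessions, in \{0,3,6\}) and
#'   `rng_seed`.
#' @examples
#' assign_design(c("P01", "P02"), seed = 42)
#' @export
assign_design <- function(participant_ids, seed = NULL) {
  if (length(participant_ids) == 0) {
    stop("participant_ids must be non-empty", call. = FALSE)
  }
  participant_ids <- as.character(participant_ids)
  if (anyDuplicated(participant_ids)) {
    stop("participant_ids must be unique", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(participant_ids)
  tibble::tibble(
    participant_id = participant_ids,
    baseline_length = sample(c(4L, 5L, 6L), n, replace = TRUE),
    addon_start = sample(c(0L, 3L, 6L), n, replace = TRUE),
    rng_seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Materialize the phase calendar for one design assignment
#'
#' Expands an assignment into contiguous, non-overlapping week ranges:
#' phase A spans `baseline_length` weeks from week 0; the intervention
#' spans `n_intervention_weeks`, of which the first `addon_start`
#' session-weeks are phase B and the remainder phase B2 (the add-on
#' period; `addon_start = 0` makes B empty); the follow-up phase C holds
#' exactly 3 weekly measurement slots starting `followup_gap_weeks` after
#' the intervention ends (default 26 weeks, i.e. 6 months posttreatment).
#' Sessions are identified with weeks, matching weekly treatment coaching.
#'
#' @param assignment one-row data frame as returned by [assign_design()]
#'   (or a list with `participant_id`, `baseline_length`, `addon_start`).
#' @param n_intervention_weeks total weeks in phases B + B2; must be at
#'   least `addon_start`.
#' @param followup_gap_weeks weeks between the end of the intervention and
#'   the first follow-up measurement.
#' @return a `phase_schedule`: list with `participant_id`, integer week
#'   vectors `A`, `B`, `B2`, `C`, and `addon_start_week`.
#' @examples
#' a <- assign_design("P01", seed = 1)
#' phase_schedule(a, n_intervention_weeks = 10)
#' @export
phase_schedule <- function(assignment, n_intervention_weeks,
                           followup_gap_weeks = 26) {
  bl <- as.integer(assignment$baseline_length)
  addon <- as.integer(assignment$addon_start)
  stopifnot(length(bl) == 1, length(addon) == 1,
            bl %in% c(4L, 5L, 6L), addon %in% c(0L, 3L, 6L),
            followup_gap_weeks >= 0)
  n_intervention_weeks <- as.integer(n_intervention_weeks)
  if (n_intervention_weeks < addon) {
    stop("n_intervention_weeks (", n_intervention_weeks,
         ") is smaller than addon_start (", addon, ")", call. = FALSE)
  }
  a_weeks <- seq_len(bl) - 1L
  b_weeks <- if (addon > 0) bl + seq_len(addon) - 1L else integer()
  b2_weeks <- if (n_intervention_weeks > addon) {
    bl + addon + seq_len(n_intervention_weeks - addon) - 1L
  } else integer()
  c_start <- bl + n_intervention_weeks + as.integer(followup_gap_weeks)
  c_weeks <- c_start + 0:2
  structure(
    list(participant_id = as.character(assignment$participant_id),
         A = a_weeks, B = b_weeks, B2 = b2_weeks, C = c_weeks,
         addon_start_week = bl + addon),
    class = "phase_schedule"
  )
}

#' @export
print.phase_schedule <- function(x, ...) {
  rng <- function(w) if (length(w)) paste0(min(w), "-", max(w)) else "(empty)"
  cat("<phase_schedule> participant", x$participant_id, "\n")
  cat("  A :", rng(x$A), " B :", rng(x$B), " B2:", rng(x$B2),
      " C :", rng(x$C), "\n")
  cat("  add-on starts week", x$addon_start_week, "\n")
  invisible(x)
}

#' Phase label for each scheduled week
#'
#' @param schedule a [phase_schedule()].
#' @return tibble with columns `week_index` and `phase`, one row per
#'   scheduled weekly measurement slot.
#' @export
schedule_weeks <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  tibble::tibble(
    week_index = c(schedule$A, schedule$B, schedule$B2, schedule$C),
    phase = rep(c("A", "B", "B2", "C"),
                times = c(length(schedule$A), length(schedule$B),
                          length(schedule$B2), length(schedule$C)))
  )
}

#' Read/write design assignments as CSV
#'
#' @param design tibble as returned by [assign_design()].
#' @param path file path.
#' @return the path / the assignments tibble.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  normalize_design(raw)
}
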