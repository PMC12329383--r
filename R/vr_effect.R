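#' Configuration of the VR session-difference analysis
#'
#' @param positive_cap ceiling applied to the positive-following composite
#'   before differencing (default 30: once a parent shows the 10 labeled
#'   praises + 10 reflections + 10 behavior descriptions of the mastery
#'   criterion, higher tallies are treated as equivalent).
#' @param min_practices minimum number of home VR practices between two
#'   coded sessions for the pair to qualify (default 1).
#' @param group_split_cutoff total VR practice count at or below which a
#'   participant falls in the low-use group (default 6, i.e. groups of
#'   6-or-fewer vs 7-or-more practices).
#' @return a `vr_effect_config` list.
#' @export
vr_effect_config <- function(positive_cap = 30, min_practices = 1,
                             group_split_cutoff = 6) {
  stopifnot(positive_cap > 0, min_practices >= 0, group_split_cutoff >= 0)
  structure(list(positive_cap = positive_cap,
                 min_practices = min_practices,
                 group_split_cutoff = group_split_cutoff),
            class = "vr_effect_config")
}

#' Cap a positive-following count at the mastery-equivalent ceiling
#'
#' @param count non-negative count(s).
#' @param cap ceiling (default 30).
#' @return `pmin(count, cap)`.
#' @export
cap_positive <- function(count, cap = 30) {
  if (any(count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  pmin(count, cap)
}

#' Session-to-session DPICS differences around VR practice
#'
#' For each pair of consecutive archived sessions of one participant with
#' at least `min_practices` VR practices logged in between, computes the
#' change in the capped positive-following composite and the (uncapped)
#' negative-leading composite: a positive `d_pf` and a negative `d_nl`
#' are the hypothesized benefit of practicing. Sessions missing from the
#' record (uncoded or unarchived) simply break the chain: differences are
#' taken between sessions adjacent in the archive, never interpolated.
#'
#' @param sessions session tibble of one or more participants (see
#'   [study_dataset()]).
#' @param config a [vr_effect_config()].
#' @return tibble with columns `participant_id`, `session_from`,
#'   `session_to`, `vr_practices`, `d_pf` (capped), `d_nl`.
#' @export
session_diffs <- function(sessions, config = vr_effect_config()) {
  sessions <- normalize_sessions(sessions)
  out <- list()
  for (pid in unique(sessions$participant_id)) {
    s <- sessions[sessions$participant_id == pid, ]
    s <- s[order(s$session_index), ]
    if (nrow(s) < 2) next
    pf <- cap_positive(positive_following(s), config$positive_cap)
    nl <- negative_leading(s)
    later <- 2:nrow(s)
    qualifies <- s$vr_practices_since_previous[later] >= config$min_practices
    if (!any(qualifies)) next
    sel <- later[qualifies]
    out[[length(out) + 1L]] <- tibble::tibble(
      participant_id = pid,
      session_from = s$session_index[sel - 1L],
      session_to = s$session_index[sel],
      vr_practices = s$vr_practices_since_previous[sel],
      d_pf = pf[sel] - pf[sel - 1L],
      d_nl = nl[sel] - nl[sel - 1L])
  }
  if (!length(out)) {
    return(tibble::tibble(participant_id = character(),
                          session_from = integer(), session_to = integer(),
                          vr_practices = integer(), d_pf = integer(),
                          d_nl = integer()))
  }
  dplyr::bind_rows(out)
}

#' Median and mean of session differences per participant
#'
#' @param diffs output of [session_diffs()].
#' @return tibble with one row per participant: `n_pairs`,
#'   `median_d_pf`, `median_d_nl`, `mean_d_pf`, `mean_d_nl` (the median of
#'   an even-length list is the mean of the two middle values).
#'   Participants with no qualifying pairs yield no row.
#' @export
summarize_diffs <- function(diffs) {
  if (nrow(diffs) == 0) {
    return(tibble::tibble(participant_id = character(), n_pairs = integer(),
                          median_d_pf = double(), median_d_nl = double(),
                          mean_d_pf = double(), mean_d_nl = double()))
  }
  dplyr::summarise(
    dplyr::group_by(diffs, .data$participant_id),
    n_pairs = dplyr::n(),
    median_d_pf = stats::median(.data$d_pf),
    median_d_nl = stats::median(.data$d_nl),
    mean_d_pf = mean(.data$d_pf),
    mean_d_nl = mean(.data$d_nl),
    .groups = "drop")
}

#' Split participants by total VR practice
#'
#' Deterministic two-group split of total practice counts at a configured
#' cutoff: totals at or below the cutoff form the low-use group, totals
#' above it the high-use group. The default cutoff of 6 reproduces the
#' operational 6-or-fewer vs 7-or-more grouping used for descriptive
#' comparison of practice intensity.
#'
#' @param totals named numeric vector (or tibble with `participant_id`
#'   and `total`) of total VR practices per participant.
#' @param cutoff split point (default 6).
#' @return tibble with columns `participant_id`, `total`, `vr_group`
#'   (`"low"`/`"high"`).
#' @export
split_by_use <- function(totals, cutoff = 6) {
  if (is.data.frame(totals)) {
    tab <- tibble::tibble(participant_id = as.character(totals$participant_id),
                          total = as.numeric(totals$total))
  } else {
    tab <- tibble::tibble(
      participant_id = if (is.null(names(totals)))
        as.character(seq_along(totals)) else names(totals),
      total = as.numeric(totals))
  }
  if (any(tab$total < 0, na.rm = TRUE)) {
    stop("totals must be non-negative", call. = FALSE)
  }
  tab$vr_group <- ifelse(tab$total <= cutoff, "low", "high")
  tab
}

#' VR practice totals per participant
#'
#' Sums the logged VR practices over a participant's session records.
#'
#' @param dataset a [study_dataset()].
#' @return tibble with `participant_id`, `total`.
#' @export
vr_totals <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  dplyr::summarise(
    dplyr::group_by(dataset$sessions, .data$participant_id),
    total = sum(.data$vr_practices_since_previous, na.rm = TRUE),
    .groups = "drop")
}

#' Session-difference table conditioned on VR practice
#'
#' The per-participant analogue of a "does the next session look better
#' after practicing?" table: session-to-session changes in the capped
#' positive-following and the negative-leading composite, restricted to
#' session pairs with VR practice in between, summarised as median and
#' mean per participant.
#'
#' @param dataset a [study_dataset()].
#' @param config a [vr_effect_config()].
#' @return the [summarize_diffs()] tibble; the qualifying pair-level
#'   differences are attached as attribute `"pairs"`.
#' @export
vr_effect_table <- function(dataset, config = vr_effect_config()) {
  stopifnot(inherits(dataset, "study_dataset"))
  diffs <- session_diffs(dataset$sessions, config)
  out <- summarize_diffs(diffs)
  attr(out, "pairs") <- diffs
  out
}
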