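#' DPICS session tallies
#'
#' The Dyadic Parent-Child Interaction Coding System (DPICS) tallies
#' parent verbalizations in a standardized 5-minute observation into eight
#' categories. `dpics_tally()` builds a validated one-row tally;
#' the composite and mastery functions below also accept data frames with
#' the eight category columns and operate row-wise.
#'
#' @param labeled_praise,unlabeled_praise,reflection,behavior_description
#'   counts of the four "positive following" categories.
#' @param question,direct_command,indirect_command,negative_talk counts of
#'   the four "negative leading" categories.
#' @return a one-row tibble of class `dpics_tally`.
#' @examples
#' t <- dpics_tally(labeled_praise = 10, reflection = 10,
#'                  behavior_description = 10)
#' positive_following(t)
#' mastery_met(t)
#' @export
dpics_tally <- function(labeled_praise = 0, unlabeled_praise = 0,
                        reflection = 0, behavior_description = 0,
                        question = 0, direct_command = 0,
                        indirect_command = 0, negative_talk = 0) {
  counts <- c(labeled_praise = labeled_praise,
              unlabeled_praise = unlabeled_praise,
              reflection = reflection,
              behavior_description = behavior_description,
              question = question, direct_command = direct_command,
              indirect_command = indirect_command,
              negative_talk = negative_talk)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("DPICS tallies must be non-negative integers", call. = FALSE)
  }
  out <- tibble::as_tibble(
    as.list(stats::setNames(as.integer(counts), dpics_categories())))
  class(out) <- c("dpics_tally", class(out))
  out
}

tally_matrix <- function(tally) {
  cats <- dpics_categories()
  if (is.data.frame(tally)) {
    missing_cols <- setdiff(cats, names(tally))
    if (length(missing_cols)) {
      stop("tally lacks DPICS category column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(tally[, cats])
  } else {
    missing_cols <- setdiff(cats, names(tally))
    if (length(missing_cols)) {
      stop("tally lacks DPICS category field(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    m <- matrix(as.numeric(unlist(tally[cats])), nrow = 1,
                dimnames = list(NULL, cats))
  }
  storage.mode(m) <- "double"
  m
}

#' DPICS composites: positive following and negative leading
#'
#' `positive_following()` sums labeled praise, unlabeled praise,
#' reflection and behavior description -- the child-centred skills parents
#' are coached to use. `negative_leading()` sums question, direct command,
#' indirect command and negative talk -- the verbalizations parents are
#' coached to avoid during child-directed interaction. Together the two
#' composites partition all eight coded categories.
#'
#' @param tally a [dpics_tally()], a list with the eight category fields,
#'   or a data frame with the eight category columns (row-wise result).
#' @return integer vector of composite counts.
#' @export
positive_following <- function(tally) {
  m <- tally_matrix(tally)
  as.integer(rowSums(m[, c("labeled_praise", "unlabeled_praise",
                           "reflection", "behavior_description"),
                       drop = FALSE]))
}

#' @rdname positive_following
#' @export
negative_leading <- function(tally) {
  m <- tally_matrix(tally)
  as.integer(rowSums(m[, c("question", "direct_command",
                           "indirect_command", "negative_talk"),
                       drop = FALSE]))
}

#' CDI mastery criterion
#'
#' Parents progress from the child-directed to the parent-directed phase
#' of PCIT once a 5-minute observation shows at least 10 labeled praises,
#' 10 reflective statements and 10 behavior descriptions with no
#' questions, commands, or criticisms. Criticisms are carried by the DPICS
#' negative-talk category, which subsumes them; unlabeled praise counts
#' toward the positive-following composite but carries no mastery minimum.
#'
#' @param min_labeled_praise,min_reflection,min_behavior_description
#'   per-category minima.
#' @param max_questions_commands_criticism maximum allowed total of
#'   question + direct command + indirect command + negative talk.
#' @return a `mastery_criterion` list.
#' @export
mastery_criterion <- function(min_labeled_praise = 10,
                              min_reflection = 10,
                              min_behavior_description = 10,
                              max_questions_commands_criticism = 0) {
  stopifnot(min_labeled_praise >= 0, min_reflection >= 0,
            min_behavior_description >= 0,
            max_questions_commands_criticism >= 0)
  structure(list(min_labeled_praise = min_labeled_praise,
                 min_reflection = min_reflection,
                 min_behavior_description = min_behavior_description,
                 max_questions_commands_criticism =
                   max_questions_commands_criticism),
            class = "mastery_criterion")
}

#' @rdname mastery_criterion
#' @param tally a tally (see [positive_following()] for accepted forms).
#' @param criterion a [mastery_criterion()].
#' @return `mastery_met()`: logical vector, `TRUE` where the criterion is
#'   met.
#' @export
mastery_met <- function(tally, criterion = mastery_criterion()) {
  m <- tally_matrix(tally)
  neg <- rowSums(m[, c("question", "direct_command", "indirect_command",
                       "negative_talk"), drop = FALSE])
  m[, "labeled_praise"] >= criterion$min_labeled_praise &
    m[, "reflection"] >= criterion$min_reflection &
    m[, "behavior_description"] >= criterion$min_behavior_description &
    neg <= criterion$max_questions_commands_criticism
}

#' Between-coder agreement for a double-coded observation
#'
#' Per-category agreement is the min/max ratio of the two coders' counts
#' (1 when both are zero, 0 when exactly one is zero), averaged over the
#' eight categories and expressed as a percentage. This transparent
#' count-ratio index is the package's own convention; published DPICS
#' reliability figures do not disclose their agreement formula, so values
#' are comparable in spirit but not necessarily numerically.
#'
#' @param tally_a,tally_b two tallies of the same observation.
#' @return agreement percentage in \[0, 100\].
#' @examples
#' coder_agreement(dpics_tally(question = 4), dpics_tally(question = 5))
#' @export
coder_agreement <- function(tally_a, tally_b) {
  a <- as.numeric(tally_matrix(tally_a)[1, ])
  b <- as.numeric(tally_matrix(tally_b)[1, ])
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ratio <- ifelse(hi == 0, 1, lo / hi)
  100 * mean(ratio)
}

#' Read/write per-session DPICS tally CSV
#'
#' Columns: `participant_id`, `session_index`, the eight DPICS categories,
#' and `vr_practices_since_previous` (number of home VR practice sessions
#' logged since the previous coded session).
#'
#' @param sessions session tibble (see [study_dataset()]).
#' @param path file path.
#' @export
write_sessions_csv <- function(sessions, path) {
  utils::write.csv(sessions, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_sessions_csv
#' @export
read_sessions_csv <- function(path) {
  raw <- utils::read.csv(path)
  normalize_sessions(raw)
}
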