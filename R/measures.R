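#' Measure and phase vocabularies
#'
#' The package stores every score in a long table keyed by a measure token
#' and a phase token. `sced_measures()` lists the recognised measures with
#' their admissible score ranges; `sced_phases()` lists the phase labels.
#'
#' Phases `A`, `B`, `B2`, `C` label the weekly series (baseline,
#' intervention, intervention with the VR add-on, follow-up). `B2` encodes
#' what design diagrams usually write as B-prime; prime characters are
#' hostile in file formats. `T0`, `T1`, `T2` label the pre/post/follow-up
#' assessment occasions, which carry no week-ordering constraint relative
#' to the weekly rows.
#'
#' Default ranges follow the standard instruments: the ECBI Intensity scale
#' is a 36-item 7-point scale (raw range 36-252), the ECBI Problem scale a
#' 36-item yes/no count (0-36). OBVL(-K) parenting-stress totals are
#' T-scores and left unbounded; DPICS composites and VR practice counts are
#' non-negative integers. Ranges can be overridden via the `ranges`
#' argument of [study_dataset()] for non-standard scorings.
#'
#' @return `sced_measures()`: a tibble with columns `measure`, `min`,
#'   `max`, `integer` (whether values must be whole numbers).
#'   `sced_phases()`: a character vector of phase tokens.
#' @examples
#' sced_measures()
#' sced_phases()
#' @export
sced_measures <- function() {
  tibble::tibble(
    measure = c("ECBI_INTENSITY", "ECBI_PROBLEM", "OBVL_K",
                "DPICS_PF", "DPICS_NL", "VR_COUNT"),
    min     = c(36, 0, -Inf, 0, 0, 0),
    max     = c(252, 36, Inf, Inf, Inf, Inf),
    integer = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
}

#' @rdname sced_measures
#' @export
sced_phases <- function() c("A", "B", "B2", "C", "T0", "T1", "T2")

#' @rdname sced_measures
#' @export
weekly_phases <- function() c("A", "B", "B2", "C")

#' @rdname sced_measures
#' @export
assessment_phases <- function() c("T0", "T1", "T2")

# dropout vocabulary (Table-1-style footnote categories)
dropout_levels <- function() c("completer", "dropped_intervention", "dropped_fully")

dpics_categories <- function() {
  c("labeled_praise", "unlabeled_praise", "reflection", "behavior_description",
    "question", "direct_command", "indirect_command", "negative_talk")
}
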