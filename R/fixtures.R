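#' Bundled example data: a PCIT-VR multiple-baseline study
#'
#' Small plain-text tables from a published single-case experimental
#' study of Parent-Child Interaction Therapy with a staggered
#' virtual-reality practice add-on, shipped so the package's worked
#' examples and checks run without any download. Eleven parents (labelled
#' by their study ids) contributed pre/post/follow-up assessments of the
#' DPICS composites, the ECBI Intensity and Problem scales, and OBVL
#' parenting-stress totals, together with their total VR practice counts
#' and dropout status; one participant dropped out of the intervention
#' but remained in the study, and two entered during the intervention and
#' so lack pretreatment scores.
#'
#' `pcitvr_assessments()` returns the raw assessment scores as a
#' [study_dataset()] (long form, phases `T0`/`T1`/`T2`).
#' `pcitvr_randomization()` returns the study's reported per-participant
#' randomization-test results (Cohen's d, one-sided p) for the two weekly
#' questionnaires -- the weekly series themselves were published only as
#' figures, so the individual p-values are data here, inputs to the group
#' combination. `pcitvr_rci_published()` returns the reliable change
#' indices as published, including two cells known to be inconsistent
#' with the raw scores (participant 15's Intensity T0-T2/T1-T2 values and
#' participant 16's Problem column), kept verbatim for comparison against
#' recomputation.
#'
#' @return see above; all tables are tibbles except the assessment
#'   dataset.
#' @examples
#' ds <- pcitvr_assessments()
#' timepoint_stats(timepoint_sample(ds, "DPICS_PF", "T0")$value)
#' @export
pcitvr_assessments <- function() {
  path <- system.file("extdata", "pcitvr_assessments.csv",
                      package = "mbsced", mustWork = TRUE)
  raw <- utils::read.csv(path, colClasses = "character")
  obs <- tibble::tibble(
    participant_id = raw$participant_id,
    measure = raw$measure,
    week_index = NA_integer_,
    phase = raw$timepoint,
    value = as.numeric(raw$value))
  parts <- unique(tibble::tibble(participant_id = raw$participant_id,
                                 dropout_status = raw$dropout_status))
  ds <- study_dataset(obs, participants = parts)
  vr <- unique(tibble::tibble(participant_id = raw$participant_id,
                              total = as.numeric(raw$vr_total)))
  attr(ds, "vr_totals") <- vr
  ds
}

#' @rdname pcitvr_assessments
#' @export
pcitvr_randomization <- function() {
  path <- system.file("extdata", "pcitvr_randomization.csv",
                      package = "mbsced", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(
    path, colClasses = c("character", "character", "character",
                         "numeric", "numeric")))
}

#' @rdname pcitvr_assessments
#' @export
pcitvr_rci_published <- function() {
  path <- system.file("extdata", "pcitvr_rci_published.csv",
                      package = "mbsced", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(
    path, colClasses = c("character", "character", "character", "numeric")))
}
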