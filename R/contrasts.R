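#' Restrict a dataset by dropout status
#'
#' Pre/post/follow-up group analyses include only participants who stayed
#' in the study: participants flagged `dropped_fully` are removed
#' entirely, and participants flagged `dropped_intervention` (left
#' treatment but kept completing measurements) are, by default, retained
#' -- their exclusion from specific timepoint aggregates is handled by
#' [timepoint_sample()].
#'
#' @param dataset a [study_dataset()].
#' @param include_dropped_intervention keep participants who dropped out
#'   of the intervention but remained in the study (default `TRUE`).
#' @return a filtered `study_dataset`.
#' @export
completer_filter <- function(dataset, include_dropped_intervention = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  keep_status <- c("completer",
                   if (include_dropped_intervention) "dropped_intervention")
  keep <- dataset$participants$participant_id[
    dataset$participants$dropout_status %in% keep_status]
  subset_dataset(dataset, keep)
}

subset_dataset <- function(dataset, ids) {
  structure(
    list(
      participants = dataset$participants[
        dataset$participants$participant_id %in% ids, ],
      observations = dataset$observations[
        dataset$observations$participant_id %in% ids, ],
      sessions = dataset$sessions[
        dataset$sessions$participant_id %in% ids, ],
      design = dataset$design[
        dataset$design$participant_id %in% ids, ]
    ),
    class = "study_dataset"
  )
}

#' One timepoint's sample of assessment scores
#'
#' Collects the non-missing scores of one measure at one assessment
#' occasion. Participants who dropped out fully are always excluded;
#' participants who dropped out of the intervention but remained in the
#' study are excluded from post- and follow-up (`T1`, `T2`) aggregates --
#' their later assessments no longer reflect a completed treatment -- but
#' contribute to `T0`.
#'
#' @param dataset a [study_dataset()].
#' @param measure measure token.
#' @param timepoint `"T0"`, `"T1"` or `"T2"`.
#' @return tibble with columns `participant_id`, `value`.
#' @export
timepoint_sample <- function(dataset, measure, timepoint) {
  stopifnot(inherits(dataset, "study_dataset"),
            timepoint %in% assessment_phases())
  parts <- dataset$participants
  excluded_status <- c("dropped_fully",
                       if (timepoint %in% c("T1", "T2")) "dropped_intervention")
  keep_ids <- parts$participant_id[!parts$dropout_status %in% excluded_status]
  obs <- dataset$observations
  sel <- obs$participant_id %in% keep_ids & obs$measure == measure &
    obs$phase == timepoint & !is.na(obs$value)
  tibble::tibble(participant_id = obs$participant_id[sel],
                 value = obs$value[sel])
}

#' Descriptive statistics for a timepoint sample
#'
#' @param values numeric vector of non-missing scores (e.g. the `value`
#'   column of [timepoint_sample()]).
#' @return tibble with `n`, `mean`, `sd` (sample SD, `NA` when n < 2),
#'   `min`, `max`.
#' @export
timepoint_stats <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no values to summarise", call. = FALSE)
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
    min = min(values),
    max = max(values)
  )
}

#' Exact Wilcoxon signed-rank test for paired scores
#'
#' Two-sided paired signed-rank test suited to the very small samples of
#' single-case group summaries. Zero differences are dropped and tied
#' absolute differences receive midranks. For 25 or fewer informative
#' pairs the null distribution of the positive-rank sum V is computed
#' exactly by enumerating sign assignments through a convolution over the
#' (midrank-resolved) ranks, so exact p-values remain available under
#' ties, where the closed-form tables do not apply. Larger samples fall
#' back on the normal approximation with tie correction and continuity
#' correction.
#'
#' @param pre,post paired numeric vectors; pairs with a missing member
#'   are dropped.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`
#'   (two-sided), `n_pairs` (informative pairs after dropping zeros),
#'   `exact` (logical). All differences zero gives p = 1 with a warning.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(4, 5, 7))$p_value # 0.25
#' @export
wilcoxon_signed_rank <- function(pre, post) {
  pre <- as.numeric(pre)
  post <- as.numeric(post)
  stopifnot(length(pre) == length(post))
  ok <- !is.na(pre) & !is.na(post)
  d <- post[ok] - pre[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, n_pairs = 0L, exact = TRUE))
  }
  r <- rank(abs(d))           # midranks for ties
  v <- sum(r[d > 0])
  if (n <= 25) {
    # exact null: each rank enters V with probability 1/2 independently;
    # doubling makes midranks integral for the convolution.
    r2 <- as.integer(round(2 * r))
    probs <- c(1)             # P(2V = 0), then convolve rank by rank
    for (ri in r2) {
      shifted <- c(rep(0, ri), probs)
      probs <- (c(probs, rep(0, ri)) + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    cdf_lo <- sum(probs[seq_len(v2 + 1L)])            # P(2V <= v2)
    cdf_hi <- sum(probs[(v2 + 1L):length(probs)])     # P(2V >= v2)
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  list(statistic = v, p_value = p, n_pairs = as.integer(n), exact = exact)
}

#' Cohen's d between two assessment occasions
#'
#' Two variants are reported because they answer different questions and
#' can disagree substantially in small samples: `"pooled"` standardizes
#' the mean difference of the two (possibly differently sized) samples by
#' their (n-1)-weighted pooled SD; `"paired"` standardizes the mean
#' within-pair change by the SD of the paired differences and requires
#' equal-length paired input.
#'
#' @param sample_a,sample_b numeric score vectors (paired order for
#'   `variant = "paired"`); missing values (or pairs) are dropped.
#' @param variant `"pooled"` or `"paired"`.
#' @return Cohen's d for the b-minus-a change.
#' @export
cohens_d_timepoints <- function(sample_a, sample_b,
                                variant = c("pooled", "paired")) {
  variant <- match.arg(variant)
  a <- as.numeric(sample_a)
  b <- as.numeric(sample_b)
  if (variant == "pooled") {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      stop("pooled variant needs >= 2 values per sample", call. = FALSE)
    }
    sp <- pooled_sd(a, b)
    if (sp == 0) stop("zero pooled SD; d undefined", call. = FALSE)
    (mean(b) - mean(a)) / sp
  } else {
    stopifnot(length(a) == length(b))
    ok <- !is.na(a) & !is.na(b)
    d <- b[ok] - a[ok]
    if (length(d) < 2) stop("paired variant needs >= 2 pairs", call. = FALSE)
    s <- stats::sd(d)
    if (s == 0) stop("zero difference SD; d undefined", call. = FALSE)
    mean(d) / s
  }
}

#' Timepoint contrast table (pre/post/follow-up group outcomes)
#'
#' For each measure, summarises the T0/T1/T2 samples (after the dropout
#' exclusions of [timepoint_sample()]) and tests the three pairwise
#' contrasts with the exact Wilcoxon signed-rank test on complete pairs,
#' reporting both Cohen's d variants.
#'
#' @param dataset a [study_dataset()].
#' @param measures measure tokens (default the two DPICS composites).
#' @return list of two tibbles: `descriptives` (measure, timepoint, n,
#'   mean, sd, min, max) and `contrasts` (measure, contrast, n_pairs,
#'   statistic, p_value, d_pooled, d_paired).
#' @export
contrast_table <- function(dataset, measures = c("DPICS_PF", "DPICS_NL")) {
  stopifnot(inherits(dataset, "study_dataset"))
  desc <- list()
  ctr <- list()
  pairs <- list(c("T0", "T1"), c("T0", "T2"), c("T1", "T2"))
  for (ms in measures) {
    samples <- lapply(assessment_phases(), function(tp)
      timepoint_sample(dataset, ms, tp))
    names(samples) <- assessment_phases()
    for (tp in assessment_phases()) {
      if (nrow(samples[[tp]]) == 0) next
      st <- timepoint_stats(samples[[tp]]$value)
      desc[[length(desc) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(measure = ms, timepoint = tp), st)
    }
    for (pr in pairs) {
      s1 <- samples[[pr[1]]]
      s2 <- samples[[pr[2]]]
      common <- intersect(s1$participant_id, s2$participant_id)
      if (length(common) < 2) next
      v1 <- s1$value[match(common, s1$participant_id)]
      v2 <- s2$value[match(common, s2$participant_id)]
      w <- suppressWarnings(wilcoxon_signed_rank(v1, v2))
      d_pooled <- tryCatch(cohens_d_timepoints(v1, v2, "pooled"),
                           error = function(e) NA_real_)
      d_paired <- tryCatch(cohens_d_timepoints(v1, v2, "paired"),
                           error = function(e) NA_real_)
      ctr[[length(ctr) + 1L]] <- tibble::tibble(
        measure = ms, contrast = paste(pr, collapse = "-"),
        n_pairs = w$n_pairs, statistic = w$statistic, p_value = w$p_value,
        d_pooled = d_pooled, d_paired = d_paired)
    }
  }
  list(descriptives = dplyr::bind_rows(desc), contrasts = dplyr::bind_rows(ctr))
}
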