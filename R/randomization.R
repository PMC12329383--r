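#' Phase comparison for the per-participant randomization test
#'
#' Pairs one participant's baseline (phase A) values with their
#' intervention (phases B and B2) values, together with the therapeutic
#' direction of the measure. Questionnaire scores (ECBI, OBVL-K) are
#' expected to decrease under effective treatment
#' (`"decrease_is_effect"`); skill counts such as DPICS positive following
#' would use `"increase_is_effect"`. Participants need at least 2
#' measurement points in each phase to be testable.
#'
#' @param baseline numeric vector of phase-A values, in week order.
#' @param intervention numeric vector of intervention-phase values, in
#'   week order.
#' @param direction `"decrease_is_effect"` or `"increase_is_effect"`.
#' @return a `phase_comparison` list.
#' @export
phase_comparison <- function(baseline, intervention,
                             direction = c("decrease_is_effect",
                                           "increase_is_effect")) {
  direction <- match.arg(direction)
  baseline <- as.numeric(baseline)
  intervention <- as.numeric(intervention)
  if (anyNA(baseline) || anyNA(intervention)) {
    stop("phase values must be non-missing (drop NAs before comparison)",
         call. = FALSE)
  }
  if (length(baseline) < 2 || length(intervention) < 2) {
    stop("at least 2 measurement points are required in each phase ",
         "(got ", length(baseline), " baseline, ", length(intervention),
         " intervention)", call. = FALSE)
  }
  structure(list(baseline = baseline, intervention = intervention,
                 direction = direction),
            class = "phase_comparison")
}

as_phase_comparison <- function(comparison, intervention = NULL,
                                direction = "decrease_is_effect") {
  if (inherits(comparison, "phase_comparison")) return(comparison)
  phase_comparison(comparison, intervention, direction)
}

direction_sign <- function(direction) {
  if (direction == "decrease_is_effect") 1 else -1
}

#' Cohen's d between study phases
#'
#' Standardized mean difference between baseline and intervention values,
#' using the (n-1)-weighted pooled standard deviation. The sign is
#' oriented so that therapeutic change is positive: for
#' `"decrease_is_effect"` measures d = (mean baseline - mean
#' intervention) / s_pooled, and the sign is flipped for
#' `"increase_is_effect"`. A contratherapeutic shift therefore prints
#' negative.
#'
#' @param comparison a [phase_comparison()], or a numeric baseline vector
#'   if `intervention` is supplied.
#' @param intervention optional intervention values (vector interface).
#' @param direction therapeutic direction (vector interface).
#' @return Cohen's d (numeric scalar).
#' @examples
#' cohens_d(c(10, 12, 14), c(4, 6, 8)) # pooled SD 2 -> d = 3
#' @export
cohens_d <- function(comparison, intervention = NULL,
                     direction = "decrease_is_effect") {
  cmp <- as_phase_comparison(comparison, intervention, direction)
  a <- cmp$baseline
  b <- cmp$intervention
  sp <- pooled_sd(a, b)
  if (sp == 0) {
    stop("degenerate variance: pooled SD is zero, Cohen's d is undefined",
         call. = FALSE)
  }
  direction_sign(cmp$direction) * (mean(a) - mean(b)) / sp
}

pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
}

#' Descriptive label for an effect-size magnitude
#'
#' Benchmark thresholds: 0.01 very small, 0.20 small, 0.50 medium,
#' 0.80 large, 1.20 very large, 2.00 huge. Annotation only; no analysis
#' decision depends on it.
#'
#' @param d Cohen's d value(s).
#' @return character vector of labels (based on |d|).
#' @export
effect_size_label <- function(d) {
  cuts <- c(0.01, 0.2, 0.5, 0.8, 1.2, 2)
  labels <- c("negligible", "very small", "small", "medium", "large",
              "very large", "huge")
  labels[findInterval(abs(d), cuts) + 1L]
}

#' Per-participant randomization test
#'
#' Monte-Carlo randomization test of the phase difference for a single
#' participant. The observed Cohen's d is compared with its distribution
#' over `n_resamples` random rearrangements of that participant's own
#' scores; the one-sided p-value is the fraction of resampled d values at
#' least as large as the observed one, floored at `1/n_resamples` so the
#' smallest reportable p at 1000 resamples is 0.001.
#'
#' Two resampling schemes are exposed:
#' \describe{
#'   \item{`label_permutation`}{each resample randomly reassigns the
#'     pooled scores to pseudo-phases of the original sizes (random
#'     draws from the individual scores). Default.}
#'   \item{`startpoint_shift`}{each resample moves the intervention start
#'     point across the admissible weeks of the observed series (at least
#'     2 points on each side), preserving the series order -- the
#'     design-consistent alternative for a randomized start point.}
#' }
#' Resampled splits in which both pseudo-phases are constant get d = 0
#' when their means agree and +/-Inf otherwise, so every resample is
#' comparable with the observed d.
#'
#' @inheritParams cohens_d
#' @param n_resamples number of Monte-Carlo resamples (default 1000).
#' @param scheme resampling scheme, see Details.
#' @param seed optional integer seed for reproducibility.
#' @return a `randomization_result` list: `d_obs`, `p`, `n_resamples`,
#'   `scheme`, `direction`, `seed`.
#' @examples
#' r <- randomization_p(phase_comparison(c(9, 8, 9, 10), c(1, 2, 1, 2)),
#'                      n_resamples = 500, seed = 1)
#' r$p
#' @export
randomization_p <- function(comparison, intervention = NULL,
                            direction = "decrease_is_effect",
                            n_resamples = 1000,
                            scheme = c("label_permutation",
                                       "startpoint_shift"),
                            seed = NULL) {
  cmp <- as_phase_comparison(comparison, intervention, direction)
  scheme <- match.arg(scheme)
  stopifnot(n_resamples >= 1)
  if (!is.null(seed)) set.seed(seed)

  d_obs <- cohens_d(cmp)  # errors on degenerate observed variance
  pooled <- c(cmp$baseline, cmp$intervention)
  n <- length(pooled)
  na <- length(cmp$baseline)
  dsign <- direction_sign(cmp$direction)

  if (scheme == "label_permutation") {
    idx <- vapply(seq_len(n_resamples),
                  function(i) sample.int(n, na), integer(na))
    d_star <- split_d(pooled, matrix(idx, nrow = na), dsign)
  } else {
    splits <- 2:(n - 2)
    if (length(splits) < 2) {
      stop("startpoint_shift needs at least 2 admissible start points ",
           "(>= 2 measurements on each side)", call. = FALSE)
    }
    d_at_split <- vapply(splits, function(k) {
      split_d(pooled, matrix(seq_len(k), ncol = 1), dsign)
    }, numeric(1))
    d_star <- d_at_split[sample.int(length(splits), n_resamples,
                                    replace = TRUE)]
  }

  # reference value computed through the same code path as the resamples,
  # so permutations that exactly reproduce the observed split count as ties
  d_ref <- split_d(pooled, matrix(seq_len(na), ncol = 1), dsign)
  tol <- 1e-9 * max(1, abs(d_ref))
  p <- max(sum(d_star >= d_ref - tol) / n_resamples, 1 / n_resamples)
  structure(list(d_obs = d_obs, p = p, n_resamples = as.integer(n_resamples),
                 scheme = scheme, direction = cmp$direction,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "randomization_result")
}

# d for each column of index matrix idx (indices of the pseudo-baseline
# within `pooled`); vectorized over resamples via sufficient statistics.
split_d <- function(pooled, idx, dsign) {
  na <- nrow(idx)
  n <- length(pooled)
  nb <- n - na
  va <- matrix(pooled[idx], nrow = na)
  s_tot <- sum(pooled)
  q_tot <- sum(pooled^2)
  s_a <- colSums(va)
  q_a <- colSums(va^2)
  m_a <- s_a / na
  m_b <- (s_tot - s_a) / nb
  ss_a <- pmax(q_a - na * m_a^2, 0)
  ss_b <- pmax((q_tot - q_a) - nb * m_b^2, 0)
  sp <- sqrt((ss_a + ss_b) / (n - 2))
  diff <- dsign * (m_a - m_b)
  ifelse(sp > 0, diff / sp, ifelse(diff == 0, 0, sign(diff) * Inf))
}

#' @export
print.randomization_result <- function(x, ...) {
  cat("<randomization_result> scheme:", x$scheme, "\n")
  cat(sprintf("  d = %.3f (%s), one-sided p = %.3g (%d resamples)\n",
              x$d_obs, effect_size_label(x$d_obs), x$p, x$n_resamples))
  invisible(x)
}

#' Irwin-Hall cumulative distribution function
#'
#' Exact CDF of the sum of `n` independent Uniform(0,1) variables,
#' evaluated with the alternating-sum polynomial
#' \deqn{F_n(x) = \frac{1}{n!} \sum_{k=0}^{\lfloor x\rfloor} (-1)^k
#'   \binom{n}{k} (x-k)^n,}
#' clamped to \[0, 1\]. Under the group null hypothesis that every
#' participant's individual p-value is Uniform(0,1), the group p-value of
#' the additive combination is this CDF evaluated at the sum of the
#' individual p-values. Numerically dependable for `n` up to about 50,
#' which covers any realistic single-case series count.
#'
#' @param x quantile(s); values outside \[0, n\] return 0 or 1.
#' @param n positive integer number of uniform summands.
#' @return probabilities in \[0, 1\], vectorized over `x`.
#' @examples
#' irwin_hall_cdf(0.5, 1)  # 0.5
#' irwin_hall_cdf(1, 2)    # 0.5 by symmetry of the triangular density
#' @export
irwin_hall_cdf <- function(x, n) {
  stopifnot(length(n) == 1, n >= 1, n == round(n))
  n <- as.integer(n)
  vapply(as.numeric(x), function(xi) {
    if (is.na(xi)) return(NA_real_)
    if (xi <= 0) return(0)
    if (xi >= n) return(1)
    k <- 0:floor(xi)
    terms <- (-1)^k * exp(lchoose(n, k) + n * log(xi - k) - lfactorial(n))
    min(max(sum(terms), 0), 1)
  }, numeric(1))
}

#' Combine individual p-values into a group p-value
#'
#' Additive combination for replicated single-case tests: the test
#' statistic is the sum S of the participants' individual one-sided
#' p-values, referred to its null distribution under which each p is
#' Uniform(0,1) -- the Irwin-Hall distribution. Small S (many small
#' individual p-values) yields a small group p.
#'
#' @param individual_ps numeric vector of p-values in (0, 1].
#' @param method `"irwin_hall_exact"` (exact CDF, default),
#'   `"normal_approx"` (CLT approximation with mean n/2 and variance
#'   n/12), or `"monte_carlo"` (empirical fraction of simulated uniform
#'   sums at or below S).
#' @param n_sim Monte-Carlo sample size for `method = "monte_carlo"`.
#' @param seed optional seed for `method = "monte_carlo"`.
#' @return a `group_combination` list: `individual_ps`, `S`, `group_p`,
#'   `method`, `n`.
#' @examples
#' combine_p(c(0.20, 0.68, 0.50, 0.92, 0.24, 0.001, 0.27, 0.28))
#' @export
combine_p <- function(individual_ps,
                      method = c("irwin_hall_exact", "normal_approx",
                                 "monte_carlo"),
                      n_sim = 1e5, seed = NULL) {
  method <- match.arg(method)
  individual_ps <- as.numeric(individual_ps)
  if (length(individual_ps) == 0) {
    stop("individual_ps must be non-empty", call. = FALSE)
  }
  if (anyNA(individual_ps) || any(individual_ps <= 0 | individual_ps > 1)) {
    stop("individual p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(individual_ps)
  S <- sum(individual_ps)
  group_p <- switch(
    method,
    irwin_hall_exact = irwin_hall_cdf(S, n),
    normal_approx = stats::pnorm((S - n / 2) / sqrt(n / 12)),
    monte_carlo = {
      if (!is.null(seed)) set.seed(seed)
      sums <- colSums(matrix(stats::runif(n * n_sim), nrow = n))
      mean(sums <= S)
    }
  )
  structure(list(individual_ps = individual_ps, S = S, group_p = group_p,
                 method = method, n = n),
            class = "group_combination")
}

#' @export
print.group_combination <- function(x, ...) {
  cat("<group_combination>", x$method, "over", x$n, "participants\n")
  cat(sprintf("  S = %.4f, group p = %.4f\n", x$S, x$group_p))
  invisible(x)
}

#' Randomization-test table for a study dataset
#'
#' Runs the per-participant randomization test for each requested measure
#' and appends group rows combining the individual p-values with the exact
#' uniform-sum method -- one row for treatment completers only and one for
#' all tested participants. Participants lacking 2 non-missing points in
#' the baseline or in the intervention phases are excluded and listed in
#' the `"excluded"` attribute with the reason.
#'
#' @param dataset a [study_dataset()].
#' @param measures measures to test (default the two weekly
#'   questionnaires).
#' @param intervention_phases phases pooled as "intervention" (default B
#'   and B2).
#' @param direction therapeutic direction for all requested measures.
#' @inheritParams randomization_p
#' @return tibble with columns `participant_id`, `measure`, `n_baseline`,
#'   `n_intervention`, `d`, `effect_label`, `p`, `row_type`
#'   (`"participant"`, `"completers"`, `"total"`); group rows carry `NA`
#'   d. Attribute `"excluded"`: tibble of skipped participants.
#' @export
randomization_table <- function(dataset,
                                measures = c("ECBI_INTENSITY", "OBVL_K"),
                                intervention_phases = c("B", "B2"),
                                direction = "decrease_is_effect",
                                n_resamples = 1000,
                                scheme = "label_permutation",
                                seed = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!is.null(seed)) set.seed(seed)
  parts <- dataset$participants
  rows <- list()
  excluded <- list()
  for (ms in measures) {
    for (pid in parts$participant_id) {
      a <- extract_phase(dataset, pid, ms, "A")
      b <- extract_phase(dataset, pid, ms, intervention_phases)
      if (length(a) < 2 || length(b) < 2) {
        if (length(a) + length(b) > 0) {
          excluded[[length(excluded) + 1L]] <- tibble::tibble(
            participant_id = pid, measure = ms,
            reason = sprintf("fewer than 2 points per phase (%d baseline, %d intervention)",
                             length(a), length(b)))
        }
        next
      }
      res <- tryCatch(
        randomization_p(phase_comparison(a, b, direction),
                        n_resamples = n_resamples, scheme = scheme),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1L]] <- tibble::tibble(
          participant_id = pid, measure = ms, reason = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, measure = ms,
        n_baseline = length(a), n_intervention = length(b),
        d = res$d_obs, effect_label = effect_size_label(res$d_obs),
        p = res$p, row_type = "participant")
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab)) {
    status <- parts$dropout_status[match(tab$participant_id,
                                         parts$participant_id)]
    group_rows <- list()
    for (ms in unique(tab$measure)) {
      sel <- tab$measure == ms & tab$row_type == "participant"
      comp <- sel & status == "completer"
      for (grp in c("completers", "total")) {
        use <- if (grp == "completers") comp else sel
        if (sum(use) == 0) next
        gc <- combine_p(tab$p[use])
        group_rows[[length(group_rows) + 1L]] <- tibble::tibble(
          participant_id = grp, measure = ms,
          n_baseline = NA_integer_, n_intervention = NA_integer_,
          d = NA_real_, effect_label = NA_character_,
          p = gc$group_p, row_type = grp)
      }
    }
    tab <- dplyr::bind_rows(tab, dplyr::bind_rows(group_rows))
  }
  attr(tab, "excluded") <- dplyr::bind_rows(excluded)
  tab
}
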