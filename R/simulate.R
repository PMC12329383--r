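#' Configuration of the synthetic SCED generator
#'
#' Generates multiple-baseline study datasets with the statistical
#' structure the analysis pipeline assumes: per-participant weekly series
#' with phase-dependent means and AR(1) within-person noise, DPICS
#' session tallies trending toward the mastery mix during the
#' intervention, VR practice counts appearing only once the add-on phase
#' (B2) starts, and missingness/dropout processes. Defaults emulate a
#' community-based clinical PCIT sample: 11 families of which roughly 7
#' in 11 enrol both parents (about 18 participants), weekly ECBI
#' Intensity around 150, OBVL-K T-scores around 72, low baseline positive
#' following and high baseline negative leading. Within-person SDs are
#' stand-ins chosen to look like weekly questionnaire noise; published
#' single-case reports rarely print them.
#'
#' @param n_families number of families (>= 1).
#' @param prob_two_parent probability a family enrols two parents; the
#'   two parents share the child's ECBI series but have independent
#'   parenting-stress and DPICS series.
#' @param baseline_mean,within_sd named vectors over the five simulated
#'   measures.
#' @param effect_b,effect_b2 level changes (raw units) applied during
#'   phase B and additionally during phase B2; therapeutic signs are
#'   negative for the questionnaires and negative-leading, positive for
#'   positive following.
#' @param slope named vector of weekly slopes during the intervention.
#' @param pf_ceiling,nl_floor soft bounds toward which the DPICS
#'   composite means saturate (mastery-like skill levels).
#' @param rho AR(1) autocorrelation of the within-person noise, in
#'   \[0, 0.6\].
#' @param p_missing probability each weekly questionnaire measurement is
#'   missed.
#' @param dropout_hazard per-week probability of dropping out during the
#'   intervention.
#' @param keep_assessments_on_dropout if `TRUE` a dropout keeps its
#'   post/follow-up assessments (status `dropped_intervention`),
#'   otherwise loses them (status `dropped_fully`).
#' @param vr_rate mean VR practices per week while the add-on is active.
#' @param n_intervention_weeks,followup_gap_weeks schedule constants
#'   passed to [phase_schedule()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(
    n_families = 11,
    prob_two_parent = 7 / 11,
    baseline_mean = c(ECBI_INTENSITY = 150, ECBI_PROBLEM = 18, OBVL_K = 72,
                      DPICS_PF = 4, DPICS_NL = 30),
    within_sd = c(ECBI_INTENSITY = 10, ECBI_PROBLEM = 3, OBVL_K = 4,
                  DPICS_PF = 2, DPICS_NL = 6),
    effect_b = c(ECBI_INTENSITY = -15, ECBI_PROBLEM = -4, OBVL_K = -4,
                 DPICS_PF = 6, DPICS_NL = -6),
    effect_b2 = c(ECBI_INTENSITY = -5, ECBI_PROBLEM = -1, OBVL_K = -1,
                  DPICS_PF = 4, DPICS_NL = -4),
    slope = c(ECBI_INTENSITY = -0.5, ECBI_PROBLEM = -0.1, OBVL_K = -0.2,
              DPICS_PF = 2, DPICS_NL = -2),
    pf_ceiling = 35, nl_floor = 2,
    rho = 0.2, p_missing = 0.1, dropout_hazard = 0.01,
    keep_assessments_on_dropout = TRUE,
    vr_rate = 1.5, n_intervention_weeks = 14, followup_gap_weeks = 26) {
  stopifnot(n_families >= 1, prob_two_parent >= 0, prob_two_parent <= 1,
            all(within_sd >= 0), rho >= 0, rho <= 0.6,
            p_missing >= 0, p_missing <= 1,
            dropout_hazard >= 0, dropout_hazard <= 1, vr_rate >= 0)
  structure(list(n_families = as.integer(n_families),
                 prob_two_parent = prob_two_parent,
                 baseline_mean = baseline_mean, within_sd = within_sd,
                 effect_b = effect_b, effect_b2 = effect_b2, slope = slope,
                 pf_ceiling = pf_ceiling, nl_floor = nl_floor,
                 rho = rho, p_missing = p_missing,
                 dropout_hazard = dropout_hazard,
                 keep_assessments_on_dropout = keep_assessments_on_dropout,
                 vr_rate = vr_rate,
                 n_intervention_weeks = as.integer(n_intervention_weeks),
                 followup_gap_weeks = as.integer(followup_gap_weeks)),
            class = "simulation_config")
}

# stationary AR(1) Gaussian noise with marginal SD `sd`
ar1_noise <- function(n, rho, sd) {
  if (n == 0) return(numeric())
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    z <- stats::rnorm(n - 1, 0, sd * sqrt(1 - rho^2))
    for (t in 2:n) e[t] <- rho * e[t - 1] + z[t - 1]
  }
  e
}

# phase-dependent mean path of one measure over the scheduled weeks
measure_mu <- function(ms, weeks_tab, schedule, config) {
  mu0 <- config$baseline_mean[[ms]]
  eb <- config$effect_b[[ms]]
  eb2 <- config$effect_b2[[ms]]
  sl <- config$slope[[ms]]
  t_int <- schedule$addon_start_week - length(schedule$B)  # intervention start
  mu <- numeric(nrow(weeks_tab))
  for (i in seq_len(nrow(weeks_tab))) {
    ph <- weeks_tab$phase[i]
    w <- weeks_tab$week_index[i]
    mu[i] <- switch(
      ph,
      A = mu0,
      B = mu0 + eb + sl * (w - t_int + 1),
      B2 = mu0 + eb + eb2 + sl * (w - t_int + 1),
      C = {
        w_end <- t_int + config$n_intervention_weeks - 1
        base <- mu0 + eb + sl * (w_end - t_int + 1)
        if (length(schedule$B2)) base + eb2 else base
      })
  }
  if (ms == "DPICS_PF") mu <- pmin(mu, config$pf_ceiling)
  if (ms == "DPICS_NL") mu <- pmax(mu, config$nl_floor)
  clamp_measure(mu, ms)
}

clamp_measure <- function(x, ms) {
  rng <- sced_measures()
  i <- match(ms, rng$measure)
  pmin(pmax(x, rng$min[i]), rng$max[i])
}

finalize_measure <- function(x, ms) {
  rng <- sced_measures()
  i <- match(ms, rng$measure)
  x <- pmin(pmax(x, rng$min[i]), rng$max[i])
  if (rng$integer[i]) round(x) else x
}

#' Simulate one participant's series and session records
#'
#' Weekly values are phase-dependent means plus stationary AR(1) noise,
#' clamped to the instrument range and rounded for count-like measures.
#' DPICS composites are also expanded into eight-category session tallies
#' (multinomial split, shifting toward the mastery mix as skills grow) for
#' the intervention weeks; VR practice counts are Poisson draws that only
#' occur from the B2 start onwards. Missingness and dropout are applied
#' after generation.
#'
#' @param config a [simulation_config()].
#' @param assignment one-row design assignment (see [assign_design()]).
#' @param participant_id label for the generated participant.
#' @param ecbi_shared optional list of pre-generated ECBI weekly series
#'   and assessments (used to share the child's behavior ratings between
#'   two parents of one family).
#' @return list with `observations` (long tibble), `sessions` (tibble),
#'   `dropout_status`, and `ecbi` (the shareable ECBI component).
#' @export
simulate_participant <- function(config, assignment,
                                 participant_id = assignment$participant_id,
                                 ecbi_shared = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  schedule <- phase_schedule(assignment, config$n_intervention_weeks,
                             config$followup_gap_weeks)
  weeks <- schedule_weeks(schedule)
  int_weeks <- weeks[weeks$phase %in% c("B", "B2"), ]

  measures <- names(config$baseline_mean)
  values <- list()
  for (ms in measures) {
    wk <- if (ms %in% c("DPICS_PF", "DPICS_NL")) int_weeks else
      weeks[weeks$phase %in% c("A", "B", "B2", "C"), ]
    mu <- measure_mu(ms, wk, schedule, config)
    raw <- mu + ar1_noise(nrow(wk), config$rho, config$within_sd[[ms]])
    values[[ms]] <- tibble::tibble(
      participant_id = participant_id, measure = ms,
      week_index = wk$week_index, phase = wk$phase,
      value = finalize_measure(raw, ms))
  }
  if (!is.null(ecbi_shared)) {
    values$ECBI_INTENSITY <- transform_pid(ecbi_shared$weekly$ECBI_INTENSITY,
                                           participant_id)
    values$ECBI_PROBLEM <- transform_pid(ecbi_shared$weekly$ECBI_PROBLEM,
                                         participant_id)
  }

  # VR counts: zero until the add-on starts, Poisson afterwards
  vr_weeks <- weeks[weeks$phase %in% c("B", "B2"), ]
  vr_counts <- integer(nrow(vr_weeks))
  active <- vr_weeks$phase == "B2"
  vr_counts[active] <- stats::rpois(sum(active), config$vr_rate)
  values$VR_COUNT <- tibble::tibble(
    participant_id = participant_id, measure = "VR_COUNT",
    week_index = vr_weeks$week_index, phase = vr_weeks$phase,
    value = vr_counts)

  # assessments: T0 at baseline level, T1/T2 at end-of-intervention level
  assess <- list()
  for (ms in setdiff(measures, character())) {
    mu0 <- measure_mu(ms, tibble::tibble(week_index = 0L, phase = "A"),
                      schedule, config)
    mu1 <- measure_mu(ms, tibble::tibble(
      week_index = schedule$C[1], phase = "C"), schedule, config)
    vals <- finalize_measure(
      c(mu0, mu1, mu1) + stats::rnorm(3, 0, config$within_sd[[ms]]), ms)
    assess[[ms]] <- tibble::tibble(
      participant_id = participant_id, measure = ms,
      week_index = NA_integer_, phase = c("T0", "T1", "T2"), value = vals)
  }
  if (!is.null(ecbi_shared)) {
    assess$ECBI_INTENSITY <- transform_pid(ecbi_shared$assess$ECBI_INTENSITY,
                                           participant_id)
    assess$ECBI_PROBLEM <- transform_pid(ecbi_shared$assess$ECBI_PROBLEM,
                                         participant_id)
  }

  ecbi <- list(
    weekly = list(ECBI_INTENSITY = values$ECBI_INTENSITY,
                  ECBI_PROBLEM = values$ECBI_PROBLEM),
    assess = list(ECBI_INTENSITY = assess$ECBI_INTENSITY,
                  ECBI_PROBLEM = assess$ECBI_PROBLEM))

  obs <- dplyr::bind_rows(c(values, assess))

  # missingness on weekly questionnaire rows
  weekly_q <- obs$phase %in% weekly_phases() &
    obs$measure %in% c("ECBI_INTENSITY", "ECBI_PROBLEM", "OBVL_K")
  miss <- weekly_q & stats::runif(nrow(obs)) < config$p_missing
  obs$value[miss] <- NA_real_

  # dropout: per-week hazard over the baseline + intervention weeks
  dropout_status <- "completer"
  risk_weeks <- weeks$week_index[weeks$phase %in% c("A", "B", "B2")]
  if (config$dropout_hazard > 0 && length(risk_weeks)) {
    hit <- which(stats::runif(length(risk_weeks)) < config$dropout_hazard)
    if (length(hit)) {
      drop_week <- risk_weeks[hit[1]]
      keep <- !(obs$phase %in% weekly_phases() &
                  !is.na(obs$week_index) & obs$week_index > drop_week)
      obs <- obs[keep, ]
      if (config$keep_assessments_on_dropout) {
        dropout_status <- "dropped_intervention"
      } else {
        dropout_status <- "dropped_fully"
        obs <- obs[!(obs$phase %in% c("T1", "T2")), ]
      }
    }
  }

  sessions <- build_sessions(obs, participant_id)
  list(observations = obs, sessions = sessions,
       dropout_status = dropout_status, ecbi = ecbi)
}

transform_pid <- function(tab, pid) {
  tab$participant_id <- pid
  tab
}

# expand the weekly PF/NL composites into eight-category tallies; the
# category mix drifts from a question/command-heavy profile toward the
# mastery mix (labeled praise / reflection / behavior description) as the
# positive composite grows.
build_sessions <- function(obs, participant_id) {
  pf <- obs[obs$measure == "DPICS_PF" & obs$phase %in% c("B", "B2"), ]
  nl <- obs[obs$measure == "DPICS_NL" & obs$phase %in% c("B", "B2"), ]
  vr <- obs[obs$measure == "VR_COUNT", ]
  weeks <- intersect(pf$week_index, nl$week_index)
  if (!length(weeks)) {
    return(normalize_sessions(NULL))
  }
  weeks <- sort(weeks)
  first_week <- min(weeks)
  rows <- lapply(seq_along(weeks), function(i) {
    w <- weeks[i]
    pf_i <- pf$value[pf$week_index == w]
    nl_i <- nl$value[nl$week_index == w]
    skill <- min(pf_i / 30, 1)
    p_pos <- (1 - skill) * c(0.2, 0.4, 0.2, 0.2) +
      skill * c(1, 0, 1, 1) / 3
    pos <- as.integer(stats::rmultinom(1, pf_i, p_pos))
    neg <- as.integer(stats::rmultinom(1, nl_i, c(0.4, 0.25, 0.2, 0.15)))
    vr_i <- vr$value[vr$week_index == w]
    tibble::tibble(
      participant_id = participant_id, session_index = i,
      labeled_praise = pos[1], unlabeled_praise = pos[2],
      reflection = pos[3], behavior_description = pos[4],
      question = neg[1], direct_command = neg[2],
      indirect_command = neg[3], negative_talk = neg[4],
      vr_practices_since_previous =
        if (length(vr_i)) as.integer(vr_i) else 0L)
  })
  dplyr::bind_rows(rows)
}

#' Simulate a full multiple-baseline study dataset
#'
#' Families are expanded into one or two parent participants. Both
#' parents of a two-parent family report on the same child, so they share
#' the ECBI series; their parenting-stress (OBVL-K) and DPICS series are
#' independent. Each family receives one design randomization (baseline
#' length, add-on start) shared by its parents.
#'
#' @param config a [simulation_config()].
#' @param seed optional integer seed.
#' @return a validated [study_dataset()].
#' @examples
#' ds <- simulate_dataset(simulation_config(n_families = 2), seed = 7)
#' ds
#' @export
simulate_dataset <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  fam_ids <- sprintf("F%02d", seq_len(config$n_families))
  fam_design <- assign_design(fam_ids)
  two_parent <- stats::runif(config$n_families) < config$prob_two_parent

  obs <- list(); sessions <- list(); parts <- list(); design <- list()
  pid_counter <- 0L
  for (f in seq_len(config$n_families)) {
    n_parents <- if (two_parent[f]) 2L else 1L
    shared <- NULL
    for (k in seq_len(n_parents)) {
      pid_counter <- pid_counter + 1L
      pid <- sprintf("P%02d", pid_counter)
      assignment <- fam_design[f, ]
      sim <- simulate_participant(config, assignment, participant_id = pid,
                                  ecbi_shared = shared)
      if (k == 1L) shared <- sim$ecbi
      obs[[length(obs) + 1L]] <- sim$observations
      sessions[[length(sessions) + 1L]] <- sim$sessions
      parts[[length(parts) + 1L]] <- tibble::tibble(
        participant_id = pid, dropout_status = sim$dropout_status)
      design[[length(design) + 1L]] <- tibble::tibble(
        participant_id = pid,
        baseline_length = assignment$baseline_length,
        addon_start = assignment$addon_start,
        rng_seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    }
  }
  study_dataset(observations = dplyr::bind_rows(obs),
                participants = dplyr::bind_rows(parts),
                sessions = dplyr::bind_rows(sessions),
                design = dplyr::bind_rows(design))
}

#' Calibration run: recovery of a known level change
#'
#' Simulates two-phase series with a known intervention level change
#' `delta` (in raw units, therapeutic direction: scores drop by `delta`)
#' on top of AR(1) noise, runs the per-participant randomization test on
#' each replicate, and reports the mean recovered level change and the
#' rejection rate at `alpha`. With `delta = 0` this measures the test's
#' type-I error under serial dependence `rho`; with `delta > 0` its
#' power.
#'
#' @param delta injected level change (raw units).
#' @param n_baseline,n_intervention measurement points per phase.
#' @param sd_within within-person (marginal) noise SD.
#' @param rho AR(1) autocorrelation.
#' @param n_replicates number of simulated series.
#' @param n_resamples resamples per randomization test.
#' @param alpha nominal significance level.
#' @param scheme resampling scheme (see [randomization_p()]).
#' @param seed optional integer seed.
#' @return list with `delta`, `estimate` (mean of baseline-minus-
#'   intervention means), `se` (Monte-Carlo SE of the estimate),
#'   `rejection_rate`, `n_replicates`.
#' @export
known_effect_recovery <- function(delta, n_baseline = 10,
                                  n_intervention = 10, sd_within = 1,
                                  rho = 0, n_replicates = 500,
                                  n_resamples = 1000, alpha = 0.05,
                                  scheme = "label_permutation",
                                  seed = NULL) {
  stopifnot(n_baseline >= 2, n_intervention >= 2, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  est <- numeric(n_replicates)
  rej <- logical(n_replicates)
  n_tot <- n_baseline + n_intervention
  for (i in seq_len(n_replicates)) {
    e <- ar1_noise(n_tot, rho, sd_within)
    a <- e[seq_len(n_baseline)]
    b <- e[(n_baseline + 1):n_tot] - delta
    est[i] <- mean(a) - mean(b)
    r <- randomization_p(phase_comparison(a, b, "decrease_is_effect"),
                         n_resamples = n_resamples, scheme = scheme)
    rej[i] <- r$p <= alpha
  }
  list(delta = delta, estimate = mean(est),
       se = stats::sd(est) / sqrt(n_replicates),
       rejection_rate = mean(rej), n_replicates = as.integer(n_replicates))
}
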