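test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(n_families = 3)
  d1 <- simulate_dataset(cfg, seed = 101)
  d2 <- simulate_dataset(cfg, seed = 101)
  expect_equal(d1$observations, d2$observations)
  expect_equal(as.data.frame(d1$sessions), as.data.frame(d2$sessions))
  expect_equal(d1$participants, d2$participants)
  d3 <- simulate_dataset(cfg, seed = 102)
  expect_false(identical(d1$observations$value, d3$observations$value))
})

test_that("zero noise and zero effects produce constant series at the baseline means", {
  cfg <- simulation_config(
    n_families = 1, prob_two_parent = 0,
    within_sd = c(ECBI_INTENSITY = 0, ECBI_PROBLEM = 0, OBVL_K = 0,
                  DPICS_PF = 0, DPICS_NL = 0),
    effect_b = c(ECBI_INTENSITY = 0, ECBI_PROBLEM = 0, OBVL_K = 0,
                 DPICS_PF = 0, DPICS_NL = 0),
    effect_b2 = c(ECBI_INTENSITY = 0, ECBI_PROBLEM = 0, OBVL_K = 0,
                  DPICS_PF = 0, DPICS_NL = 0),
    slope = c(ECBI_INTENSITY = 0, ECBI_PROBLEM = 0, OBVL_K = 0,
              DPICS_PF = 0, DPICS_NL = 0),
    p_missing = 0, dropout_hazard = 0, vr_rate = 0)
  ds <- simulate_dataset(cfg, seed = 1)
  obs <- ds$observations
  for (ms in c("ECBI_INTENSITY", "OBVL_K")) {
    v <- obs$value[obs$measure == ms]
    expect_true(all(v == cfg$baseline_mean[[ms]]))
  }
  # zero VR rate -> all VR counts zero
  expect_true(all(obs$value[obs$measure == "VR_COUNT"] == 0))
})

test_that("generated datasets validate, respect ranges, and keep VR to the add-on phase", {
  for (seed in c(7, 8, 9)) {
    ds <- simulate_dataset(simulation_config(n_families = 4, rho = 0.4,
                                             dropout_hazard = 0.05),
                           seed = seed)
    expect_s3_class(validate_dataset(ds), "study_dataset")
    obs <- ds$observations
    vr <- obs[obs$measure == "VR_COUNT" & obs$value > 0, ]
    expect_true(all(vr$phase == "B2"))
    ecbi <- obs$value[obs$measure == "ECBI_INTENSITY" & !is.na(obs$value)]
    expect_true(all(ecbi >= 36 & ecbi <= 252 & ecbi == round(ecbi)))
  }
})

test_that("two-parent families share the child's ECBI series but not OBVL", {
  cfg <- simulation_config(n_families = 1, prob_two_parent = 1,
                           p_missing = 0, dropout_hazard = 0)
  ds <- simulate_dataset(cfg, seed = 33)
  expect_equal(nrow(ds$participants), 2)
  ids <- ds$participants$participant_id
  e1 <- extract_phase(ds, ids[1], "ECBI_INTENSITY", c("A", "B", "B2", "C"))
  e2 <- extract_phase(ds, ids[2], "ECBI_INTENSITY", c("A", "B", "B2", "C"))
  expect_equal(e1, e2)
  o1 <- extract_phase(ds, ids[1], "OBVL_K", c("A", "B", "B2", "C"))
  o2 <- extract_phase(ds, ids[2], "OBVL_K", c("A", "B", "B2", "C"))
  expect_false(identical(o1, o2))
  # parents of one family share the design assignment
  expect_equal(ds$design$baseline_length[1], ds$design$baseline_length[2])
})

test_that("family expansion matches the two-parent probability on average", {
  # with prob 7/11 and 11 families the expected participant count is 18
  counts <- vapply(1:30, function(s) {
    nrow(simulate_dataset(simulation_config(n_families = 11,
                                            dropout_hazard = 0),
                          seed = 1000 + s)$participants)
  }, numeric(1))
  expected <- 11 * (1 + 7 / 11)
  se <- sqrt(11 * (7 / 11) * (4 / 11) / 30)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # prob 0 -> participants == families
  ds0 <- simulate_dataset(simulation_config(n_families = 5,
                                            prob_two_parent = 0), seed = 4)
  expect_equal(nrow(ds0$participants), 5)
})

test_that("under rho = 0 and no effect the permutation p is close to uniform", {
  r <- known_effect_recovery(0, n_baseline = 6, n_intervention = 8,
                             n_replicates = 400, n_resamples = 400,
                             seed = 55)
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(r$rejection_rate - 0.05), 3.5 * se)
  expect_lt(abs(r$estimate - 0), 3 * r$se)
})

test_that("known_effect_recovery estimate concentrates as replicates grow", {
  r_small <- known_effect_recovery(1, n_replicates = 50, n_resamples = 200,
                                   seed = 60)
  r_big <- known_effect_recovery(1, n_replicates = 400, n_resamples = 200,
                                 seed = 61)
  expect_lt(r_big$se, r_small$se)
  expect_lt(abs(r_big$estimate - 1), 4 * r_big$se)
})
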