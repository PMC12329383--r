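test_that("analyze_study assembles all five tables with run metadata", {
  ds <- simulate_dataset(simulation_config(n_families = 3), seed = 21)
  cfg <- analysis_config(n_resamples = 200, seed = 5)
  rep <- suppressMessages(analyze_study(ds, cfg))
  expect_s3_class(rep, "analysis_report")
  expect_true(all(c("randomization", "vr_effect", "contrasts", "raw_scores",
                    "rci", "meta") %in% names(rep)))
  expect_equal(rep$meta$seed, 5)
  expect_true(nzchar(rep$meta$config_hash))
  # report cells equal direct invocation of the underlying operations
  set.seed(5)
  direct <- randomization_table(ds, n_resamples = 200)
  expect_equal(rep$randomization$p, direct$p)
  expect_equal(rep$vr_effect, vr_effect_table(ds, cfg$vr))
  expect_error(analyze_study(study_dataset(), cfg), "no analyzable")
})

test_that("the simulate -> analyze -> report pipeline is deterministic and file-complete", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(simulation_config(n_families = 2), d1, seed = 77)
  run_simulate(simulation_config(n_families = 2), d2, seed = 77)
  for (f in c("observations.csv", "sessions.csv", "design.csv",
              "participants.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  back <- load_dataset_dir(d1)
  expect_s3_class(validate_dataset(back), "study_dataset")

  r1 <- withr::local_tempdir(); r2 <- withr::local_tempdir()
  suppressMessages(run_analyze(d1, analysis_config(n_resamples = 150,
                                                   seed = 3), r1))
  suppressMessages(run_analyze(d2, analysis_config(n_resamples = 150,
                                                   seed = 3), r2))
  for (f in c("randomization_tests.csv", "vr_session_diffs.csv",
              "timepoint_descriptives.csv", "timepoint_contrasts.csv",
              "raw_scores.csv", "reliable_change.csv", "report.json")) {
    expect_true(file.exists(file.path(r1, f)))
    expect_identical(readLines(file.path(r1, f)), readLines(file.path(r2, f)))
  }
})

test_that("configs round trip through YAML including nested reliability settings", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_resamples: 250",
               "alpha: 0.01",
               "reliability:",
               "  ECBI_INTENSITY:",
               "    s_diff: 20.0",
               "    rci_threshold: 1.96",
               "    clinical_cutoff: 131"), f)
  cfg <- read_analysis_config(f)
  expect_equal(cfg$n_resamples, 250)
  expect_equal(cfg$alpha, 0.01)
  expect_equal(cfg$reliability$ECBI_INTENSITY$s_diff, 20)
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_families: 2", "vr_rate: 0"), f2)
  scfg <- read_analysis_config(f2, "simulation")
  expect_equal(scfg$n_families, 2L)
  writeLines("not_a_key: 1", f2)
  expect_error(read_analysis_config(f2, "simulation"), "unknown config key")
})

test_that("plot data carries series, phase-boundary markers and DPICS reference bands", {
  ds <- simulate_dataset(simulation_config(n_families = 2, prob_two_parent = 0,
                                           dropout_hazard = 0), seed = 31)
  pd <- plot_data(ds)
  expect_true(all(c("series", "markers", "band") %in% names(pd)))
  pid <- ds$participants$participant_id[1]
  drow <- ds$design[ds$design$participant_id == pid, ]
  mk <- pd$markers[[which(pd$participant_id == pid &
                            pd$measure == "ECBI_INTENSITY")]]
  # marker weeks equal the materialized schedule boundaries
  sched <- phase_schedule(drow, n_intervention_weeks = 14)
  expect_equal(mk$addon_start_week, sched$addon_start_week)
  if (length(sched$B)) expect_equal(mk$B_start_week, min(sched$B))
  expect_equal(mk$B2_start_week, min(sched$B2))
  expect_equal(mk$C_start_week, min(sched$C))
  # bands only on the DPICS composites, at 30 (above) and 5 (below)
  expect_equal(unique(pd$band[pd$measure == "DPICS_PF"]), 30)
  expect_equal(unique(pd$band_side[pd$measure == "DPICS_NL"]), "below")
  expect_true(all(is.na(pd$band[pd$measure == "ECBI_INTENSITY"])))

  out <- withr::local_tempdir()
  run_plotdata(ds, out)
  files <- list.files(out)
  expect_true(sprintf("%s_DPICS_PF.json", pid) %in% files)
  payload <- jsonlite::read_json(file.path(out,
                                           sprintf("%s_DPICS_PF.json", pid)))
  expect_equal(payload$band$threshold, 30)
})

test_that("participants without an add-on phase emit no add-on marker", {
  obs <- weekly_series("P1", "ECBI_INTENSITY",
                       c(150, 148, 152, 150), c(140, 138, 141, 139))
  ds <- study_dataset(obs)
  pd <- plot_data(ds)
  expect_false("addon_start_week" %in% names(pd$markers[[1]]))
  expect_false("B2_start_week" %in% names(pd$markers[[1]]))
})
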