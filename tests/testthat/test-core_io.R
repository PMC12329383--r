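test_that("long CSV parsing maps rows to observations and empty input to an empty dataset", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("participant_id,measure,week_index,phase,value", f)
  ds <- read_long_csv(f)
  expect_s3_class(ds, "study_dataset")
  expect_equal(nrow(ds$participants), 0)
  expect_equal(nrow(ds$observations), 0)

  writeLines(c("participant_id,measure,week_index,phase,value",
               "P09,ECBI_INTENSITY,3,A,151",
               "P09,ECBI_INTENSITY,4,A,"), f)
  ds <- read_long_csv(f)
  expect_equal(nrow(ds$observations), 2)
  first <- ds$observations[1, ]
  expect_equal(first$week_index, 3L)
  expect_equal(first$phase, "A")
  expect_equal(first$value, 151)
  # blank value is missing, never zero
  expect_true(is.na(ds$observations$value[2]))
})

test_that("unknown tokens and duplicate cells are rejected with row context", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,measure,week_index,phase,value",
               "P01,NOT_A_MEASURE,0,A,10"), f)
  expect_error(read_long_csv(f), "unknown measure.*NOT_A_MEASURE")

  writeLines(c("participant_id,measure,week_index,phase,value",
               "P01,ECBI_PROBLEM,0,Z,10"), f)
  expect_error(read_long_csv(f), "unknown phase.*Z")

  writeLines(c("participant_id,measure,week_index,phase,value",
               "P01,ECBI_PROBLEM,0,A,10",
               "P01,ECBI_PROBLEM,0,A,11"), f)
  expect_error(read_long_csv(f), "duplicate")
})

test_that("instrument ranges are enforced with closed bounds 36/252 and 0/36", {
  ok <- function(measure, value) {
    study_dataset(obs_row("P", measure, 0, "A", value))
  }
  expect_s3_class(ok("ECBI_INTENSITY", 36), "study_dataset")
  expect_s3_class(ok("ECBI_INTENSITY", 252), "study_dataset")
  expect_error(ok("ECBI_INTENSITY", 35), "outside the admissible range")
  expect_error(ok("ECBI_INTENSITY", 253), "outside the admissible range")
  expect_s3_class(ok("ECBI_PROBLEM", 0), "study_dataset")
  expect_s3_class(ok("ECBI_PROBLEM", 36), "study_dataset")
  expect_error(ok("ECBI_PROBLEM", -1), "outside the admissible range")
  expect_error(ok("ECBI_PROBLEM", 37), "outside the admissible range")
  expect_error(ok("VR_COUNT", 2.5), "non-integer")
  # custom ranges are honoured
  rng <- sced_measures()
  rng$max[rng$measure == "ECBI_PROBLEM"] <- 50
  expect_s3_class(
    study_dataset(obs_row("P", "ECBI_PROBLEM", 0, "A", 45), ranges = rng),
    "study_dataset")
})

test_that("CSV round trip is the identity on observations; JSON round trip on whole datasets", {
  set.seed(31)
  ds <- simulate_dataset(simulation_config(n_families = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(ds, f)
  back <- read_long_csv(f, participants = ds$participants)
  expect_equal(back$observations, ds$observations)
  # second round trip is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))

  j <- withr::local_tempfile(fileext = ".json")
  write_dataset_json(ds, j)
  back_j <- read_dataset_json(j)
  expect_equal(back_j$observations, ds$observations)
  expect_equal(back_j$participants, ds$participants)
  expect_equal(back_j$design, ds$design)
  expect_equal(as.data.frame(back_j$sessions), as.data.frame(ds$sessions))
})

test_that("extract_phase drops missing values, honours the phase set, and sorts by week", {
  obs <- rbind(
    obs_row("P1", "OBVL_K", c(3, 1, 0, 2), "A", c(70, NA, 72, 71)),
    obs_row("P1", "OBVL_K", c(5, 4), "B", c(60, 62)),
    obs_row("P1", "OBVL_K", 6, "B2", 55))
  ds <- study_dataset(obs[sample(nrow(obs)), ])
  expect_equal(extract_phase(ds, "P1", "OBVL_K", "A"), c(72, 71, 70))
  expect_equal(extract_phase(ds, "P1", "OBVL_K", c("B", "B2")), c(62, 60, 55))
  expect_equal(extract_phase(ds, "P1", "OBVL_K", "C"), numeric(0))
  expect_error(extract_phase(ds, "P1", "OBVL_K", "Q"), "unknown phase")
  # ordering matches an independent sort oracle
  a_rows <- obs[obs$phase == "A" & !is.na(obs$value), ]
  expect_equal(extract_phase(ds, "P1", "OBVL_K", "A"),
               a_rows$value[order(a_rows$week_index)])
})

test_that("phase extraction over {A} and {B,B2} partitions the weekly non-follow-up observations", {
  set.seed(77)
  ds <- simulate_dataset(simulation_config(n_families = 2))
  for (pid in ds$participants$participant_id) {
    a <- extract_phase(ds, pid, "ECBI_INTENSITY", "A")
    b <- extract_phase(ds, pid, "ECBI_INTENSITY", c("B", "B2"))
    obs <- ds$observations
    sel <- obs$participant_id == pid & obs$measure == "ECBI_INTENSITY" &
      obs$phase %in% c("A", "B", "B2") & !is.na(obs$value)
    expect_equal(length(a) + length(b), sum(sel))
    expect_equal(sort(c(a, b)), sort(obs$value[sel]))
  }
})
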