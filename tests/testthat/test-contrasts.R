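test_that("timepoint samples apply the dropout exclusion rules", {
  ds <- pcitvr_assessments()
  t0 <- timepoint_sample(ds, "DPICS_PF", "T0")
  expect_true("12" %in% t0$participant_id)   # retained at pretreatment
  t1 <- timepoint_sample(ds, "DPICS_PF", "T1")
  expect_false("12" %in% t1$participant_id)  # excluded post-dropout
  expect_equal(nrow(t1), 10)
})

test_that("timepoint_stats returns n, mean, n-1 SD and range, with edge cases", {
  st <- timepoint_stats(c(4, 4, 4))
  expect_equal(st$sd, 0)
  one <- timepoint_stats(7)
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd))
  expect_error(timepoint_stats(numeric(0)), "no values")
  st2 <- timepoint_stats(c(2, 4, 9))
  expect_equal(st2$mean, 5)
  expect_equal(st2$sd, sd(c(2, 4, 9)))
  expect_equal(c(st2$min, st2$max), c(2, 9))
})

test_that("completer_filter subsets all four component tables by status", {
  set.seed(12)
  ds <- simulate_dataset(simulation_config(n_families = 4,
                                           dropout_hazard = 0.2))
  parts <- ds$participants
  kept <- completer_filter(ds)
  expect_setequal(
    kept$participants$participant_id,
    parts$participant_id[parts$dropout_status != "dropped_fully"])
  strict <- completer_filter(ds, include_dropped_intervention = FALSE)
  expect_setequal(
    strict$participants$participant_id,
    parts$participant_id[parts$dropout_status == "completer"])
  expect_true(all(strict$observations$participant_id %in%
                    strict$participants$participant_id))
  # all completers -> identity on ids; all dropped -> empty
  ds$participants$dropout_status <- "completer"
  expect_setequal(completer_filter(ds)$participants$participant_id,
                  parts$participant_id)
  ds$participants$dropout_status <- "dropped_fully"
  expect_equal(nrow(completer_filter(ds)$participants), 0)
})

test_that("exact signed-rank p matches brute-force enumeration and wilcox.test", {
  # 3 pairs, all differences positive -> two-sided exact p = 2/8
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 4, 7))
  expect_equal(w$p_value, 0.25)
  expect_true(w$exact)
  # identical pairs -> p = 1 with warning
  expect_warning(w0 <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_equal(w0$p_value, 1)
  # all sign patterns at n = 5, tie-free: match both oracles
  set.seed(13)
  base <- c(1.3, 2.9, 4.1, 5.7, 8.2)
  for (rep in 1:10) {
    delta <- sample(c(-1, 1), 5, replace = TRUE) * runif(5, 0.3, 3)
    post <- base + delta
    w <- wilcoxon_signed_rank(base, post)
    expect_equal(w$p_value, enumerate_signed_rank_p(base, post))
    ref <- wilcox.test(post, base, paired = TRUE, exact = TRUE)
    expect_equal(w$p_value, unname(ref$p.value))
    expect_equal(w$statistic, unname(ref$statistic))
  }
  # tied |differences|: midranks, still exact, still matches enumeration
  pre <- c(10, 10, 10, 10)
  post <- c(12, 12, 8, 13)
  wt <- wilcoxon_signed_rank(pre, post)
  expect_true(wt$exact)
  expect_equal(wt$p_value, enumerate_signed_rank_p(pre, post))
})

test_that("signed-rank p is invariant to pair order and to shifting both members", {
  set.seed(14)
  pre <- rnorm(8); post <- rnorm(8)
  w <- wilcoxon_signed_rank(pre, post)
  o <- sample(8)
  expect_equal(wilcoxon_signed_rank(pre[o], post[o])$p_value, w$p_value)
  expect_equal(wilcoxon_signed_rank(pre + 5, post + 5)$p_value, w$p_value)
})

test_that("timepoint Cohen's d variants compute their closed forms and disagree in general", {
  # means 10 vs 4, both SDs 2 -> pooled d = 3 (decrease)
  a <- c(8, 10, 12); b <- c(2, 4, 6)
  expect_equal(cohens_d_timepoints(a, b, "pooled"), -3)
  expect_equal(cohens_d_timepoints(b, a, "pooled"), 3)
  expect_equal(cohens_d_timepoints(a, a, "pooled"), 0)
})

test_that("paired d standardizes by the difference SD", {
  a <- c(8, 10, 12); b <- c(9, 12, 13)
  d <- b - a
  expect_equal(cohens_d_timepoints(a, b, "paired"), mean(d) / sd(d))
  # constant differences have zero SD -> error
  expect_error(cohens_d_timepoints(a, a + 2, "paired"), "zero difference SD")
  # variants disagree in general
  expect_false(isTRUE(all.equal(cohens_d_timepoints(a, b, "pooled"),
                                cohens_d_timepoints(a, b, "paired"))))
})

test_that("contrast_table summarises the bundled assessments like the published descriptives", {
  ds <- pcitvr_assessments()
  ct <- contrast_table(ds)
  d <- ct$descriptives
  pick <- function(ms, tp) d[d$measure == ms & d$timepoint == tp, ]
  expect_equal(round(pick("DPICS_PF", "T0")$mean, 2), 5.11)
  expect_equal(round(pick("DPICS_PF", "T0")$sd, 2), 5.64)
  expect_equal(c(pick("DPICS_PF", "T0")$min, pick("DPICS_PF", "T0")$max),
               c(0, 18))
  expect_equal(round(pick("DPICS_PF", "T1")$mean, 2), 32.10)
  expect_equal(round(pick("DPICS_PF", "T2")$mean, 2), 32.00)
  expect_equal(round(pick("DPICS_NL", "T1")$mean, 2), 14.40)
  expect_equal(round(pick("DPICS_NL", "T2")$mean, 2), 6.43)
  # contrasts report exact two-sided p and both d variants
  expect_true(all(c("T0-T1", "T0-T2", "T1-T2") %in%
                    ct$contrasts$contrast[ct$contrasts$measure == "DPICS_PF"]))
  expect_true(all(ct$contrasts$p_value >= 0 & ct$contrasts$p_value <= 1))
})
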