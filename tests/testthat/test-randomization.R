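test_that("Cohen's d uses the pooled n-1 SD and is signed so therapeutic change is positive", {
  # baseline [10,12,14] vs intervention [4,6,8]: pooled SD 2 -> d = 3
  expect_equal(cohens_d(c(10, 12, 14), c(4, 6, 8)), 3)
  # identical phase means -> 0
  expect_equal(cohens_d(c(5, 7), c(6, 6, 5, 7)), 0)
  # swapping phases negates d
  set.seed(4)
  a <- rnorm(6); b <- rnorm(5) + 1
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  # increase_is_effect flips the sign
  expect_equal(cohens_d(a, b, direction = "increase_is_effect"),
               -cohens_d(a, b))
  # agreement with the plain oracle
  expect_equal(cohens_d(a, b), plain_pooled_d(a, b))
  # degenerate variance errors out
  expect_error(cohens_d(c(5, 5), c(5, 5)), "degenerate")
  # inclusion rule: at least 2 points per phase
  expect_error(phase_comparison(1, c(2, 3)), "at least 2")
})

test_that("label-permutation p matches exhaustive enumeration on tiny instances", {
  # baseline [9,8] vs intervention [1,2]: 6 label assignments, d_obs maximal
  ex <- exhaustive_label_p(c(9, 8), c(1, 2))
  expect_equal(ex$n_splits, 6)
  expect_equal(ex$p, 1 / 6)
  r <- randomization_p(phase_comparison(c(9, 8), c(1, 2)),
                       n_resamples = 6000, seed = 10)
  se <- sqrt(ex$p * (1 - ex$p) / 6000)
  expect_lt(abs(r$p - ex$p), 3 * se)
})

test_that("Monte-Carlo p is reproducible, floored at 1/n_resamples, and increases with weaker effects", {
  set.seed(30)
  hi <- rnorm(10, 20); lo <- rnorm(10, 0)
  cmp <- phase_comparison(hi, lo)
  r1 <- randomization_p(cmp, n_resamples = 1000, seed = 5)
  r2 <- randomization_p(cmp, n_resamples = 1000, seed = 5)
  expect_identical(r1$p, r2$p)
  # the observed split is essentially never redrawn (1 in C(20,10)), so the
  # count is 0 and the p-value sits at its floor instead of 0
  expect_equal(r1$p, 1 / 1000)
  # contratherapeutic direction -> p near 1
  r3 <- randomization_p(phase_comparison(lo, hi), n_resamples = 1000, seed = 5)
  expect_gt(r3$p, 0.99)
})

test_that("constant series surface a degenerate-variance error, not a p-value", {
  expect_error(
    randomization_p(phase_comparison(c(3, 3, 3), c(3, 3, 3)), seed = 1),
    "degenerate")
})

test_that("startpoint-shift scheme enumerates admissible starts and needs at least 2", {
  x <- c(10, 11, 10, 12, 4, 5, 4, 5)
  r <- randomization_p(phase_comparison(x[1:4], x[5:8]),
                       scheme = "startpoint_shift", n_resamples = 2000,
                       seed = 8)
  expect_s3_class(r, "randomization_result")
  expect_true(r$p >= 1 / 2000 && r$p <= 1)
  # only the 2:(n-2) splits are admissible; with n = 4 there is 1 -> error
  expect_error(
    randomization_p(phase_comparison(c(1, 2), c(3, 4)),
                    scheme = "startpoint_shift"),
    "admissible")
  # the observed start is among the admissible ones, so p has an atom there:
  # a monotone step series gives its smallest p at the true start
  step <- c(10, 11, 10, 11, 2, 3, 2, 3)
  rs <- randomization_p(phase_comparison(step[1:4], step[5:8]),
                        scheme = "startpoint_shift", n_resamples = 5000,
                        seed = 9)
  expect_lte(rs$p, 0.25)
})

test_that("irwin_hall_cdf has the exact small-n values, symmetry, and clamped tails", {
  expect_equal(irwin_hall_cdf(0.5, 1), 0.5)
  expect_equal(irwin_hall_cdf(1, 2), 0.5)
  expect_equal(irwin_hall_cdf(c(-1, 0, 3, 7), 3), c(0, 0, 1, 1))
  # closed form for n = 2 below the mode: x^2/2
  xs <- c(0.2, 0.5, 0.9)
  expect_equal(irwin_hall_cdf(xs, 2), xs^2 / 2)
  # symmetry F(x) + F(n - x) = 1
  for (n in c(2, 5, 8, 13)) {
    x <- seq(0.3, n - 0.3, length.out = 7)
    expect_equal(irwin_hall_cdf(x, n) + irwin_hall_cdf(n - x, n),
                 rep(1, 7), tolerance = 1e-9)
  }
  # monotone non-decreasing
  grid <- seq(0, 8, by = 0.25)
  expect_true(all(diff(irwin_hall_cdf(grid, 8)) >= -1e-12))
})

test_that("combine_p sums the p-values and the three methods agree", {
  one <- combine_p(0.5)
  expect_equal(one$group_p, 0.5)
  alln <- combine_p(rep(1, 6))
  expect_equal(alln$S, 6)
  expect_equal(alln$group_p, 1)
  expect_error(combine_p(numeric(0)), "non-empty")
  expect_error(combine_p(c(0.5, 0)), "in \\(0, 1\\]")

  ps <- c(0.04, 0.3, 0.22, 0.61, 0.09)
  exact <- combine_p(ps)$group_p
  appr <- combine_p(ps, method = "normal_approx")$group_p
  mc <- combine_p(ps, method = "monte_carlo", n_sim = 2e5, seed = 3)$group_p
  expect_lt(abs(exact - mc), 3 * sqrt(exact * (1 - exact) / 2e5))
  expect_lt(abs(exact - appr), 0.03)
})

test_that("randomization_table tests eligible series, combines groups, and logs exclusions", {
  set.seed(11)
  obs <- rbind(
    weekly_series("C1", "ECBI_INTENSITY", c(150, 155, 152, 158),
                  c(120, 118, 125, 122, 119)),
    weekly_series("C2", "ECBI_INTENSITY", c(160, 150, 155, 165),
                  c(150, 160, 148, 162, 155)),
    weekly_series("D1", "ECBI_INTENSITY", c(170, 168, 171, 169),
                  c(140, 139, 142, 141)),
    # E1 entered during the intervention: no baseline -> excluded
    obs_row("E1", "ECBI_INTENSITY", 5:9, "B", c(150, 148, 151, 149, 150)))
  parts <- data.frame(
    participant_id = c("C1", "C2", "D1", "E1"),
    dropout_status = c("completer", "completer", "dropped_fully", "completer"))
  ds <- study_dataset(obs, participants = parts)
  tab <- randomization_table(ds, measures = "ECBI_INTENSITY",
                             n_resamples = 400, seed = 21)
  ind <- tab[tab$row_type == "participant", ]
  expect_setequal(ind$participant_id, c("C1", "C2", "D1"))
  excl <- attr(tab, "excluded")
  expect_equal(excl$participant_id, "E1")
  expect_match(excl$reason, "fewer than 2 points")
  # group rows equal the exact combination of the individual p-values
  comp <- tab[tab$row_type == "completers", ]
  tot <- tab[tab$row_type == "total", ]
  expect_equal(comp$p,
               combine_p(ind$p[ind$participant_id %in% c("C1", "C2")])$group_p)
  expect_equal(tot$p, combine_p(ind$p)$group_p)
})

test_that("effect-size magnitude labels follow the benchmark cut-points", {
  expect_equal(effect_size_label(c(0.005, 0.1, 0.3, 0.6, 1, 1.5, 2.5)),
               c("negligible", "very small", "small", "medium", "large",
                 "very large", "huge"))
  expect_equal(effect_size_label(-2.17), "huge")
})
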