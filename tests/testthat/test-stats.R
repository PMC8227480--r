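test_that("summary t-test reproduces published comparisons", {
  # patient vs healthy hemispheric activation
  expect_equal(round(t_test_from_summary(218637, 162874, 24,
                                         26428, 7488, 5)$p, 3), 0.015)
  expect_equal(round(t_test_from_summary(163797, 104461, 24,
                                         15543, 2075, 5)$p, 3), 0.004)
  expect_lt(t_test_from_summary(382434, 174813, 24, 41971, 8549, 5)$p,
            0.001)
  # between-arm change comparison
  r <- t_test_from_summary(-157031, 172496, 12, 242080, 361902, 12)
  expect_equal(round(r$p, 3), 0.002)
  expect_equal(r$df, 22)
})

test_that("summary t-test degenerate cases", {
  r <- t_test_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_warning(r0 <- t_test_from_summary(1, 0, 5, 2, 0, 5))
  expect_equal(r0$p, 0)
  expect_error(t_test_from_summary(1, 1, 1, 2, 1, 5),
               class = "invalid_input")
})

test_that("pooled summary t equals the raw-data pooled t exactly", {
  set.seed(51)
  a <- rnorm(14, 1, 2)
  b <- rnorm(9, 0, 2)
  r_sum <- t_test_from_summary(mean(a), sd(a), length(a),
                               mean(b), sd(b), length(b))
  r_raw <- t.test(a, b, var.equal = TRUE)
  expect_equal(r_sum$statistic, unname(r_raw$statistic), tolerance = 1e-12)
  expect_equal(r_sum$p, r_raw$p.value, tolerance = 1e-12)
  # welch variant matches t.test default
  r_w <- t_test_from_summary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b), variant = "welch")
  r_tw <- t.test(a, b)
  expect_equal(r_w$statistic, unname(r_tw$statistic), tolerance = 1e-12)
  expect_equal(r_w$df, unname(r_tw$parameter), tolerance = 1e-9)
})

test_that("chi-square reproduces the published sex contrast", {
  r <- chi_square_proportions(5, 7, 8, 4)   # 5/12 male vs 8/12 male
  expect_equal(round(r$p, 2), 0.22)
  expect_equal(r$df, 1)
})

test_that("chi-square closed form matches stats::chisq.test", {
  set.seed(53)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 4, TRUE), 2)
    r <- chi_square_proportions(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  }
  r0 <- chi_square_proportions(6, 6, 6, 6)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(chi_square_proportions(0, 0, 3, 4), class = "invalid_table")
})

test_that("Spearman correlation: monotone extremes and tie handling", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x^3)$statistic, 1)
  expect_equal(spearman_correlation(x, -sqrt(x))$statistic, -1)
  expect_equal(spearman_correlation(x, x^3)$p, 0)
  # mid-rank tie handling against the brute-force rank formula
  xt <- c(1, 2, 2, 3, 4, 5)
  yt <- c(2, 1, 4, 3, 6, 5)
  manual <- cor(rank(xt), rank(yt))
  r <- spearman_correlation(xt, yt)
  expect_equal(r$statistic, manual, tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman",
                                   exact = FALSE))
  expect_equal(r$statistic, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5),
               class = "undefined_correlation")
  expect_error(spearman_correlation(1:3, 3:1), class = "invalid_input")
})

test_that("normality gate picks branches as the policy dictates", {
  # identical samples: rank branch, U = n1 n2 / 2, p = 1
  r <- shapiro_gate_compare(rep(3, 6), rep(3, 6))
  expect_equal(r$statistic, 18)
  expect_equal(r$p, 1)
  expect_equal(r$branch, "rank")
  # clearly normal samples at n = 12: parametric branch fires >= 85%
  set.seed(7)
  par_rate <- mean(replicate(200, {
    shapiro_gate_compare(rnorm(12), rnorm(12))$branch == "parametric"
  }))
  expect_gte(par_rate, 0.85)
  # heavy-tailed samples: rank branch in the majority
  rank_rate <- mean(replicate(200, {
    shapiro_gate_compare(rcauchy(12), rcauchy(12))$branch == "rank"
  }))
  expect_gt(rank_rate, 0.5)
  expect_error(shapiro_gate_compare(1:2, 1:5), class = "invalid_input")
})

test_that("paired gate uses differences and handles all-zero diffs", {
  a <- c(5, 6, 7, 8, 9)
  r <- shapiro_gate_compare(a, a, paired = TRUE)
  expect_equal(r$p, 1)
  set.seed(63)
  x <- rnorm(12)
  y <- x + rnorm(12, 0.5, 0.3)
  r2 <- shapiro_gate_compare(x, y, paired = TRUE)
  ref <- t.test(x, y, paired = TRUE)
  if (r2$branch == "parametric") {
    expect_equal(r2$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  expect_error(shapiro_gate_compare(1:4, 1:5, paired = TRUE),
               class = "invalid_input")
})

test_that("mixed ANOVA: null interaction by construction", {
  subj <- rep(sprintf("S%02d", 1:8), each = 3)
  tp <- rep(c("T0", "T1", "T2"), 8)
  grp <- rep(c("RAGT", "OW"), each = 12)
  traj <- rep(c(10, 14, 12), 8)            # identical time trajectories
  offs <- rep(seq(0, 7), each = 3)         # subject offsets
  tab <- data.frame(subject = subj, treatment = grp, timepoint = tp,
                    tot_auc = traj + offs)
  r <- mixed_anova_interaction(tab)
  expect_lt(r$statistic, 1e-6)
})

test_that("mixed ANOVA matches the stats::aov split-plot oracle", {
  set.seed(71)
  n_per <- 3
  subj <- rep(sprintf("S%02d", 1:(2 * n_per)), each = 3)
  grp <- rep(c("A", "B"), each = 3 * n_per)
  tp <- rep(c("T0", "T1", "T2"), 2 * n_per)
  y <- round(rnorm(6 * n_per, 10, 3) + (grp == "B") * (tp == "T2") * 4)
  tab <- data.frame(subject = subj, treatment = grp, timepoint = tp,
                    tot_auc = y)
  r <- mixed_anova_interaction(tab)
  fit <- summary(aov(tot_auc ~ treatment * timepoint +
                       Error(subject / timepoint), data = tab))
  within_tab <- fit[["Error: subject:timepoint"]][[1]]
  f_ref <- within_tab["treatment:timepoint", "F value"]
  p_ref <- within_tab["treatment:timepoint", "Pr(>F)"]
  expect_equal(r$statistic, f_ref, tolerance = 1e-9)
  expect_equal(r$p, p_ref, tolerance = 1e-9)
  expect_equal(r$df, c(2, (3 - 1) * (2 * n_per - 2)))
})

test_that("mixed ANOVA df formula gives (2, 44) for the 12+12 design", {
  set.seed(72)
  subj <- rep(sprintf("S%02d", 1:24), each = 3)
  grp <- rep(c("RAGT", "OW"), each = 36)
  tp <- rep(c("T0", "T1", "T2"), 24)
  tab <- data.frame(subject = subj, treatment = grp, timepoint = tp,
                    tot_auc = rnorm(72))
  expect_equal(mixed_anova_interaction(tab)$df, c(2, 44))
})

test_that("within-subject linear trend t-test", {
  m <- matrix(c(10, 8, 6,
                12, 9, 7,
                11, 9, 6,
                9, 8, 5), ncol = 3, byrow = TRUE)
  r <- trend_t_test(m)
  slopes <- apply(m, 1, function(v) coef(lm(v ~ I(1:3)))[2])
  ref <- t.test(slopes)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  expect_equal(r$direction, -1)
})

test_that("cohort report: schema validation and determinism", {
  tab <- simulate_cohort_table(scenario_config(n_ragt = 6, n_ow = 6,
                                               n_healthy = 5, seed = 81))
  rep1 <- analyze_cohort(tab)
  rep2 <- analyze_cohort(tab)
  expect_identical(rep1, rep2)
  expect_true(all(rep1$p >= 0 & rep1$p <= 1))
  expect_true(attr(rep1, "n_tests") == nrow(rep1))
  expect_true(any(grepl("baseline_pwms_vs_healthy", rep1$id)))
  expect_true(any(grepl("anova_interaction", rep1$id)))
  # row-order invariance
  set.seed(82)
  shuffled <- tab[sample(nrow(tab)), ]
  rep3 <- analyze_cohort(shuffled)
  expect_equal(rep3, rep1, ignore_attr = TRUE)
  # schema errors name the missing columns
  expect_error(analyze_cohort(tab[, -match("rti", names(tab))]),
               regexp = "rti", class = "schema_error")
  expect_error(analyze_cohort(tab[0, ]), class = "schema_error")
})

test_that("swapping group labels flips statistics and preserves p", {
  set.seed(83)
  a <- rnorm(12)
  b <- rnorm(12, 0.8)
  r_ab <- shapiro_gate_compare(a, b)
  r_ba <- shapiro_gate_compare(b, a)
  expect_equal(r_ab$p, r_ba$p, tolerance = 1e-9)
  if (r_ab$branch == "parametric") {
    expect_equal(r_ab$statistic, -r_ba$statistic, tolerance = 1e-9)
  }
  r1 <- t_test_from_summary(1, 1, 10, 2, 1.5, 12)
  r2 <- t_test_from_summary(2, 1.5, 12, 1, 1, 10)
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
})
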