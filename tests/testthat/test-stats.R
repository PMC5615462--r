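# fixture used across the reliability tests (4 subjects x 3 trials)
fix43 <- rbind(c(7, 9, 8), c(4, 6, 5), c(10, 12, 14), c(3, 2, 4))

test_that("ICC matches the brute-force sums-of-squares oracle", {
  ms <- ss_oracle(fix43)
  k <- 3; n <- 4
  cons <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
  agr <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  expect_equal(icc(fix43, "consistency")$value, cons, tolerance = 1e-9)
  expect_equal(icc(fix43, "agreement")$value, agr, tolerance = 1e-9)
  # independent reference values (variance-components software):
  # ICC(C,1) = 0.922680, CI 0.60-0.99; ICC(A,1) = 0.895000, CI 0.54-0.99
  expect_equal(icc(fix43, "consistency")$value, 0.922680, tolerance = 1e-6)
  expect_equal(icc(fix43, "agreement")$value, 0.895000, tolerance = 1e-6)
  expect_equal(icc(fix43, "consistency")$ci, c(0.60, 0.99), tolerance = 0.01)
  expect_equal(icc(fix43, "agreement")$ci, c(0.54, 0.99), tolerance = 0.01)
  # random matrices agree with the oracle too
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 4, 50, 10), 8, 4)
    mo <- ss_oracle(m)
    expect_equal(icc(m, "consistency")$value,
                 (mo$msr - mo$mse) / (mo$msr + 3 * mo$mse), tolerance = 1e-9)
  }
})

test_that("ICC edge cases behave", {
  ident <- rbind(c(10, 10, 10), c(20, 20, 20), c(30, 30, 30))
  expect_equal(icc(ident, "consistency")$value, 1)
  expect_equal(icc(ident, "agreement")$value, 1)
  expect_error(icc(matrix(5, 3, 3)), "zero total variance")
  expect_error(icc(fix43[1, , drop = FALSE]), "2 subjects")
  # pure noise, many subjects: ICC near zero
  set.seed(99)
  noise <- matrix(rnorm(2000 * 3), 2000, 3)
  expect_lt(abs(icc(noise, "consistency")$value), 0.08)
  # rows with missing trials are dropped listwise
  m <- rbind(fix43, c(1, NA, 2))
  r <- icc(m, "consistency")
  expect_equal(r$n, 4)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$value, icc(fix43, "consistency")$value)
})

test_that("consistency ICC dominates agreement ICC under trial bias", {
  for (seed in 1:20) {
    set.seed(seed)
    subj <- rnorm(6, 0, 6)
    m <- matrix(rnorm(6 * 3, 50, 8), 6, 3) + subj +
      matrix(rep(c(0, 2, 4), each = 6), 6, 3)   # systematic trial shift
    ms <- ss_oracle(m)
    if (ms$msc > ms$mse && ms$msr > ms$mse) {
      expect_gte(icc(m, "consistency")$value,
                 icc(m, "agreement")$value - 1e-12)
    }
  }
})

test_that("SEM is the SD of stacked consecutive differences over sqrt(2)", {
  # one subject repeats exactly, the other drifts 0 -> 0 -> 10:
  # stacked differences (0, 0, 0, 10) -> per-construction case below
  m <- rbind(c(5, 5), c(0, 10))
  # differences: 0 and 10, SD = 7.0711 -> SEM = 5.0000
  expect_equal(sem_from_differences(m)$value, 5, tolerance = 1e-9)
  expect_equal(sem_from_differences(m)$value,
               sd(c(0, 10)) / sqrt(2), tolerance = 1e-12)
  # identical trials: SEM exactly zero, a valid value
  expect_equal(sem_from_differences(rbind(c(3, 3, 3), c(8, 8, 8)))$value, 0)
  expect_error(sem_from_differences(rbind(c(1, 2))), "2 subjects")
})

test_that("SEM is shift-invariant and scales with the data", {
  set.seed(4)
  m <- matrix(rnorm(15, 70, 6), 5, 3)
  s0 <- sem_from_differences(m)$value
  expect_equal(sem_from_differences(m + 100)$value, s0, tolerance = 1e-12)
  expect_equal(sem_from_differences(m * 3)$value, 3 * s0, tolerance = 1e-12)
  expect_equal(sem_from_differences(m * -2)$value, 2 * s0, tolerance = 1e-12)
})

test_that("SEM recovers the generating within-subject noise", {
  set.seed(11)
  sems <- replicate(60, {
    m <- simulate_trial_matrix(50, 3, sd_subject = 10, sd_error = 6)
    sem_from_differences(m)$value
  })
  expect_lt(abs(mean(sems) - 6) / 6, 0.15)
})

test_that("repeated-measures ANOVA matches the oracle decomposition", {
  ms <- ss_oracle(fix43)
  a <- rm_anova(fix43)
  expect_equal(a$F, ms$msc / ms$mse, tolerance = 1e-9)
  expect_equal(a$F, 2.6, tolerance = 1e-9)
  expect_equal(a$p, 0.153745, tolerance = 1e-5)
  expect_equal(a$df1, 2); expect_equal(a$df2, 6)
  # shares its decomposition with icc()
  ic <- icc(fix43, "consistency")
  expect_equal(a$F, ic$msc / ic$mse, tolerance = 1e-12)
})

test_that("degenerate repeated-measures designs are handled", {
  # every subject improves by exactly +2 per trial with zero noise
  m <- outer(c(10, 20, 30), c(0, 2, 4), `+`)
  a <- rm_anova(m)
  expect_true(is.infinite(a$F))
  expect_equal(a$p, 0)
  expect_match(a$note, "systematic")
  expect_error(rm_anova(fix43[, 1, drop = FALSE]), "2 trials")
  expect_error(rm_anova(matrix(7, 4, 3)), "degenerate")
})

test_that("rank correlation matches hand-computed ranks", {
  r <- speed_accuracy_correlation(1:5, c(5, 4, 3, 1, 2))
  # d = (-4, -2, 0, 3, 3); rho = 1 - 6*38/120 = -0.9
  expect_equal(r$rho, -0.9, tolerance = 1e-12)
  expect_equal(r$p, 0.0373861, tolerance = 1e-5)
  expect_equal(speed_accuracy_correlation(1:6, 6:1)$rho, -1)
  expect_equal(speed_accuracy_correlation(1:6, 6:1)$p, 0)
  expect_error(speed_accuracy_correlation(1:5, rep(2, 5)), "constant")
  expect_error(speed_accuracy_correlation(1:3, 3:1), "at least 4")
  # agrees with the reference implementation on tie-free data
  set.seed(3)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  expect_equal(speed_accuracy_correlation(x, y)$rho,
               unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
})

test_that("group comparisons match the textbook formulas", {
  a <- c(71, 74, 69, 78, 73); b <- c(66, 70, 68, 71, 65)
  # paired t: d = a - b
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  r <- compare_groups(a, b, paired = TRUE)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$estimate, mean(d), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # Welch t for independent groups
  tw <- (mean(a) - mean(b)) / sqrt(var(a) / 5 + var(b) / 5)
  rw <- compare_groups(a, b)
  expect_equal(rw$t, tw, tolerance = 1e-12)
  # degenerate paired contrasts are flagged, not mis-reported
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_true(same$degenerate)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_equal(same$ci, c(0, 0))
  shift <- compare_groups(c(3, 4, 5), c(1, 2, 3), paired = TRUE)
  expect_true(shift$degenerate)
  expect_true(is.infinite(shift$t) && shift$t > 0)
})

test_that("the normality gate holds its type-I rate and detects skew", {
  set.seed(17)
  p_norm <- replicate(200, normality_gate(rnorm(50))$p)
  rate <- mean(p_norm < 0.05)
  expect_gt(rate, 0.005); expect_lt(rate, 0.12)
  p_exp <- replicate(100, normality_gate(rexp(50))$p)
  expect_gt(mean(p_exp < 0.05), 0.5)
  expect_error(normality_gate(rep(4, 10)), "constant")
  expect_error(normality_gate(c(1, 2)), "3 <= n")
})

test_that("reliability reports bundle the condition table", {
  set.seed(23)
  coh <- generate_cohort(30, learning_per_trial = 1.5, seed = 23)
  reps <- reliability_by_condition(coh$records)
  expect_length(reps, 4)
  r <- reps$left_palmar
  expect_s3_class(r, "reliability_report")
  expect_equal(r$k, 3)
  expect_equal(r$n, 30)
  m <- condition_matrix(coh$records, "acuity_pct", "left", "palmar")
  expect_equal(r$icc_consistency$value, icc(m, "consistency")$value)
  expect_equal(r$sem$value, sem_from_differences(m)$value)
  expect_equal(r$anova$F, rm_anova(m)$F)
  expect_output(print(r), "ICC consistency")
  s <- summary(r)
  expect_true(all(c("icc_consistency", "sem", "anova_F") %in% names(s)))
  # Holm adjustment is attached when requested
  reps_h <- reliability_by_condition(coh$records, holm = TRUE)
  expect_true(all(sapply(reps_h, function(x) !is.null(x$anova$p_adj))))
})
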