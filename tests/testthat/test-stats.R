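test_that("t tests match their defining algebra and conventions", {
  set.seed(2)
  x <- rnorm(20, 1)
  # identical samples: no effect
  same <- t_test(x, x, variance = "pooled")
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  # Welch df agrees with a direct evaluation of Satterthwaite's expression
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    got <- t_test(a, b, variance = "welch")
    expect_equal(got$df, welch_df_oracle(a, b), tolerance = 1e-10)
    # one-tailed p is half the two-tailed p when the effect is in-direction
    two <- t_test(a, b, tails = "two")
    dir <- if (mean(a) > mean(b)) "greater" else "less"
    one <- t_test(a, b, tails = "one", direction = dir)
    expect_equal(one$p, two$p / 2, tolerance = 1e-12)
    expect_true(one$p >= 0 && two$p <= 1)
  }
  # pooled df and d versus first principles
  a <- rnorm(12); b <- rnorm(9, 0.5)
  got <- t_test(a, b, variance = "pooled")
  expect_equal(got$df, 19)
  sp <- sqrt((11 * var(a) + 8 * var(b)) / 19)
  expect_equal(got$effect_size, (mean(a) - mean(b)) / sp)
  # zero variance in both samples with equal means is undefined
  expect_error(t_test(rep(1, 5), rep(1, 6)), "undefined")
})

test_that("summary-statistics t tests agree with raw-data t tests", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(sample(8:30, 1), 1, 2)
    b <- rnorm(sample(8:30, 1), 0, 1.5)
    for (v in c("pooled", "welch")) {
      raw <- t_test(a, b, variance = v)
      summ <- t_test_summary(mean(a), sd(a), length(a),
                             mean(b), sd(b), length(b), variance = v)
      expect_equal(summ$statistic, raw$statistic, tolerance = 1e-12)
      expect_equal(summ$df, raw$df, tolerance = 1e-12)
      expect_equal(summ$p, raw$p, tolerance = 1e-12)
      expect_equal(summ$effect_size, raw$effect_size, tolerance = 1e-12)
    }
  }
})

test_that("one-sample t of all-zero scores reports a zero statistic", {
  res <- t_test(rep(0, 10), mu = 0)
  expect_equal(res$statistic, 0)
  expect_equal(res$effect_size, 0)
})

test_that("mixed ANOVA recovers null and constructed effects", {
  set.seed(4)
  group <- rep(c("a", "b"), each = 15)
  base <- rnorm(30)
  # no change from pre to post: Time and interaction vanish
  res <- mixed_anova_2x2(base, base, group)
  expect_equal(res$F[res$effect == "Time"], 0)
  expect_equal(res$F[res$effect == "Group:Time"], 0)
  # pure additive group shift, no time change: interaction exactly null,
  # group effect present
  shifted <- base + ifelse(group == "a", 0, 3)
  res <- mixed_anova_2x2(shifted, shifted, group)
  expect_equal(res$F[res$effect == "Group:Time"], 0)
  expect_gt(res$F[res$effect == "Group"], 10)
})

test_that("mixed ANOVA agrees with the aov error-stratum oracle", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(c(6, 10, 14), 1)
    group <- rep(c("a", "b"), each = n)
    pre <- rnorm(2 * n, mean = rep(c(0, 0.5), each = n))
    post <- pre * runif(1, 0.2, 1) + rnorm(2 * n) + rep(c(0, 0.4), each = n)
    got <- mixed_anova_2x2(pre, post, group)
    want <- aov_mixed_oracle(pre, post, group)
    expect_equal(got$F[got$effect == "Group"], want$F_group, tolerance = 1e-8)
    expect_equal(got$F[got$effect == "Time"], want$F_time, tolerance = 1e-8)
    expect_equal(got$F[got$effect == "Group:Time"], want$F_int, tolerance = 1e-8)
    expect_equal(got$pes, c(want$pes_group, want$pes_time, want$pes_int),
                 tolerance = 1e-8)
  }
})

test_that("mixed ANOVA F values equal squared contrast t statistics", {
  set.seed(6)
  n <- 12
  group <- rep(c("a", "b"), each = n)
  pre <- rnorm(2 * n); post <- rnorm(2 * n, 0.3)
  res <- mixed_anova_2x2(pre, post, group)
  m <- (pre + post) / 2
  d <- post - pre
  t_group <- t.test(m[group == "a"], m[group == "b"], var.equal = TRUE)$statistic
  t_int <- t.test(d[group == "a"], d[group == "b"], var.equal = TRUE)$statistic
  expect_equal(res$F[res$effect == "Group"], unname(t_group^2), tolerance = 1e-10)
  expect_equal(res$F[res$effect == "Group:Time"], unname(t_int^2),
               tolerance = 1e-10)
})

test_that("linear contrast captures trends and vanishes for equal means", {
  set.seed(7)
  group <- rep(paste0("g", 1:4), each = 10)
  # equal group means by construction: zero contrast
  dv <- rnorm(40)
  dv <- dv - ave(dv, group) # all group means exactly 0
  res <- oneway_linear_contrast(dv, group)
  expect_equal(res$F[res$effect == "Linear"], 0)
  # near-degenerate within-group noise, perfectly linear means: the linear
  # contrast carries the whole between-group sum of squares (F_lin = 3 F_grp)
  means <- rep(1:4, each = 10)
  dv <- means + rnorm(40, sd = 1e-4)
  dv <- dv - ave(dv, group) + means  # sample means exactly linear
  res <- oneway_linear_contrast(dv, group)
  expect_equal(res$F[res$effect == "Linear"],
               3 * res$F[res$effect == "Group"], tolerance = 1e-6)
})

test_that("linear contrast equals the squared polynomial-contrast t (balanced)", {
  set.seed(8)
  for (i in 1:50) {
    g <- factor(rep(paste0("g", 1:4), each = 8))
    dv <- rnorm(32) + as.integer(g) * runif(1, 0, 0.5)
    res <- oneway_linear_contrast(dv, g)
    contrasts(g) <- contr.poly(4)
    tl <- summary(lm(dv ~ g))$coefficients["g.L", "t value"]
    expect_equal(res$F[res$effect == "Linear"], tl^2, tolerance = 1e-8)
    # omnibus F against hand-computed sums of squares
    gm <- tapply(dv, g, mean)
    ssb <- sum(8 * (gm - mean(dv))^2)
    ssw <- sum((dv - gm[g])^2)
    expect_equal(res$F[res$effect == "Group"], (ssb / 3) / (ssw / 28),
                 tolerance = 1e-8)
  }
})

test_that("empty groups are rejected", {
  expect_error(oneway_linear_contrast(c(1, 2, 3), factor(c("a", "a", "b"),
                                                         levels = c("a", "b", "c"))),
               "empty group")
})

test_that("the AIP regression matches the normal-equations oracle", {
  # 5-point dataset small enough to verify by hand algebra
  aip <- c(3, 4, 5, 7, 8)
  oip <- c(4, 5, 6, 7, 8)
  conf <- c(60, 50, 70, 40, 90)
  got <- regression_aip(aip, oip, conf)
  want <- ols_oracle(aip, oip, conf)
  expect_equal(got$estimate, want$beta[3], tolerance = 1e-10)
  expect_equal(got$statistic, want$t[3], tolerance = 1e-10)
  expect_equal(got$df, 2)
  # confidence orthogonal to the residual AIP variance: t near zero
  set.seed(9)
  oip2 <- rnorm(200)
  conf2 <- rnorm(200)
  aip2 <- 2 * oip2 + rnorm(200, sd = 1e-8)
  res <- regression_aip(aip2, oip2, conf2)
  expect_lt(abs(res$statistic), 3)
  expect_equal(res$estimate, 0, tolerance = 1e-8)
  # collinear predictors are rejected
  expect_error(regression_aip(aip, oip, 2 * oip + 1), "collinear")
})

test_that("confidence explains unique AIP variance in the modelled direction", {
  # end-to-end: lower confidence lowers the AIP (reminders become worthwhile
  # at lower values), so the confidence coefficient controlling for OIP is
  # positive and detectable at the two-group design's per-group n
  cohort <- simulate_cohort(82, default_group_params("exp1")["g1_control"],
                            master_seed = 12, collects_recall = FALSE)
  sc <- score_cohort(cohort)
  res <- regression_aip(sc$aip, sc$oip, (sc$conf_pre + sc$conf_post) / 2)
  expect_gt(res$estimate, 0)
  expect_gt(res$statistic, 2)
  expect_lt(res$p, 0.05)
})

test_that("sample-size search respects monotonicity and rejects the impossible", {
  ns <- vapply(seq(0.2, 1.2, by = 0.1),
               function(d) power_n_per_group(d, 0.05, 0.8, "one"), integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(power_n_per_group(1e-6, 0.05, 0.8, "one", n_max = 1000),
               "unattainable")
  expect_error(power_n_per_group(-1, 0.05, 0.8))
})

test_that("hindsight tests combine the one-sample and ANOVA layers coherently", {
  set.seed(10)
  group <- rep(paste0("g", 1:4), each = 30)
  hb <- rnorm(120, mean = 4, sd = 10)
  res <- hindsight_tests(hb, group)
  expect_equal(res$pooled$statistic,
               unname(t.test(hb)$statistic), tolerance = 1e-10)
  expect_identical(res$pooled$tails, "two")
  for (g in paste0("g", 1:4)) {
    expect_equal(res$per_group[[g]]$statistic,
                 unname(t.test(hb[group == g])$statistic), tolerance = 1e-10)
  }
  # group ANOVA agrees with the shared one-way computation
  an <- oneway_linear_contrast(hb, group)
  expect_equal(res$anova$F, an$F)
  # all-zero scores give the null statistic rather than an error
  null <- hindsight_tests(rep(0, 20), rep(c("a", "b"), 10))
  expect_equal(null$pooled$statistic, 0)
})
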