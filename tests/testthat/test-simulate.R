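test_that("intervention confidence updating follows the error-driven rule", {
  # zero learning rates: confidence untouched
  p0 <- participant_params(conf0 = 33, eta_pred = 0, eta_fb = 0, conf_noise = 0)
  set.seed(1)
  out <- run_intervention(p0, protocol_for("g4_full"))
  expect_equal(out$conf_after, 33)

  # control protocol never updates regardless of rates
  pc <- participant_params(conf0 = 33, eta_pred = 0.5, eta_fb = 0.5)
  set.seed(1)
  expect_equal(run_intervention(pc, protocol_for("g1_control"))$conf_after, 33)

  # hand-iterated geometric approach: c <- c + 0.5 * (70 - c), five times
  p <- participant_params(p_int = 0.7, conf0 = 20, eta_pred = 0.2, eta_fb = 0.3,
                          conf_noise = 0)
  out <- run_intervention(p, protocol_for("g3_perf_feedback"),
                          accuracies = rep(70, 5))
  expect_equal(out$conf_after, 68.4375)
  expect_length(out$practice_predictions, 5)
  # prediction-only protocol uses eta_pred alone
  out2 <- run_intervention(p, protocol_for("g2_prediction"),
                           accuracies = rep(70, 5))
  c_by_hand <- Reduce(function(c, a) c + 0.2 * (a - c), rep(70, 5), accumulate = FALSE,
                      init = 20)
  expect_equal(out2$conf_after, c_by_hand)
})

test_that("choice policy is a probit around the subjective indifference point", {
  p <- participant_params(sigma_choice = 1, delta = 0)
  # at the indifference point the reminder probability is one half
  s <- indifference_point(p, 60)
  expect_equal(s, 6)  # 60% confidence, believed-perfect reminders
  expect_equal(choice_policy(60, p, s), 0.5)
  # strictly increasing in value, decreasing in confidence, increasing in delta
  probs <- choice_policy(60, p, 2:9)
  expect_true(all(diff(probs) > 0))
  expect_true(all(choice_policy(80, p, 2:9) < probs))
  p_delta <- participant_params(sigma_choice = 1, delta = 1.5)
  expect_true(all(choice_policy(60, p_delta, 2:9) > probs))
  # vanishing choice noise gives a step function
  p_step <- participant_params(sigma_choice = 1e-9)
  expect_equal(choice_policy(60, p_step, 6.01), 1)
  expect_equal(choice_policy(60, p_step, 5.99), 0)
})

test_that("simulated records respect the trial-outcome contract", {
  p <- participant_params(p_int = 0.6, p_ext = 1.0, conf0 = 55, conf_noise = 0)
  for (seed in 1:25) {
    rec <- simulate_participant(p, protocol_for("g1_control"), seed = seed)
    tr <- rec$trials
    # perfect external accuracy: every forced-external trial scores 5/5
    expect_true(all(tr$n_correct[tr$designation == "forced_external"] == 5))
    # free trials terminate early: choice logged, no accuracy
    expect_true(all(is.na(tr$n_correct[tr$designation == "free"])))
    expect_true(all(!is.na(tr$n_correct[tr$designation != "free"])))
    # overwrite contract: forced trials execute the designated strategy
    expect_identical(tr$overwritten,
                     tr$designation != "free" &
                       tr$chosen != ifelse(tr$designation == "forced_internal",
                                           "internal", "reminder"))
    expect_true(all(tr$executed[tr$designation == "forced_internal"] == "internal"))
    expect_true(all(tr$executed[tr$designation == "free"] ==
                      tr$chosen[tr$designation == "free"]))
    # 8 free trials always match, so the applied proportion is at least 1/2
    expect_gte(mean(!tr$overwritten), 0.5)
    expect_true(all(tr$n_correct >= 0 & tr$n_correct <= 5, na.rm = TRUE))
  }
})

test_that("confidence reports are integer, clipped, and undistorted when noiseless", {
  p <- participant_params(conf0 = 50, lambda_hind = 0, conf_noise = 0)
  rec <- simulate_participant(p, protocol_for("g4_full", collects_recall = TRUE),
                              seed = 3)
  expect_identical(rec$conf_recalled, rec$conf_pre)  # no hindsight distortion
  p_hi <- participant_params(conf0 = 99, conf_noise = 30)
  confs <- vapply(1:30, function(s) {
    r <- simulate_participant(p_hi, protocol_for("g1_control"), seed = s)
    c(r$conf_pre, r$conf_post)
  }, numeric(2))
  expect_true(all(confs >= 0 & confs <= 100))
  expect_true(all(confs == round(confs)))
})

test_that("cohorts are reproducible and sized like the study designs", {
  a <- simulate_cohort(5, default_group_params("exp1"), master_seed = 99)
  b <- simulate_cohort(5, default_group_params("exp1"), master_seed = 99)
  expect_identical(a, b)
  expect_length(simulate_cohort(82, default_group_params("exp1"), 1), 164L)
  # four-group design at 104 per group gives the 416-participant sample
  spec4 <- default_group_params("exp2")
  expect_identical(length(spec4), 4L)
  expect_length(simulate_cohort(2, spec4, 1), 8L)
  expect_error(simulate_cohort(5, list(bogus = list(p_int = c(0.5, 0.1))), 1),
               "named list")
  bad <- default_group_params("exp1")
  bad$g1_control$p_int <- c(0.5)  # not a mean/sd pair
  expect_error(simulate_cohort(5, bad, 1), "mean, sd")
})

test_that("feedback learning improves calibration of the confidence report", {
  # matched seeds, 500 per arm: with feedback the mean absolute gap between
  # reported confidence and true internal accuracy must shrink
  gap <- function(eta_fb, seed) {
    set.seed(seed)
    mean(vapply(1:500, function(i) {
      conf0 <- pmin(100, pmax(0, stats::rnorm(1, 50, 25)))
      p_int <- pmin(0.98, pmax(0.05, stats::rnorm(1, 0.66, 0.15)))
      p <- participant_params(p_int = p_int, conf0 = conf0, eta_pred = 0.05,
                              eta_fb = eta_fb, conf_noise = 3)
      out <- run_intervention(p, protocol_for("g4_full"))
      abs(out$conf_after - 100 * p_int)
    }, numeric(1)))
  }
  expect_lt(gap(0.25, seed = 21), gap(0, seed = 21))
})

test_that("hindsight distortion pulls recalled confidence toward accuracy", {
  set.seed(8)
  hb <- vapply(1:200, function(i) {
    p <- participant_params(p_int = runif(1, 0.3, 0.95), conf0 = runif(1, 5, 95),
                            lambda_hind = 0.3, conf_noise = 3)
    rec <- simulate_participant(p, protocol_for("g1_control", collects_recall = TRUE))
    sc <- compute_biases(rec)
    sc$hindsight_bias
  }, numeric(1))
  expect_gt(mean(hb), 0)
  expect_gt(t.test(hb)$statistic, 2)
})
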