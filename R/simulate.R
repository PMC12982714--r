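#' Generative participant parameters
#'
#' Bundles and validates the parameters of the generative participant model.
#' The model is deliberately simple: per-target accuracy is Bernoulli with
#' strategy-specific rates; strategy choice is a probit function of target
#' value around a confidence-derived subjective indifference point; the
#' practice-phase intervention updates confidence by an error-driven rule;
#' recall of initial confidence is linearly distorted toward actual
#' performance.
#'
#' @param p_int per-target accuracy under internal memory, in (0, 1).
#' @param p_ext per-target accuracy under external reminders, in (0, 1),
#'   typically >= 0.9.
#' @param conf0 initial confidence, percent 0--100.
#' @param eta_pred learning rate applied when the participant makes a
#'   practice prediction (engagement effect alone), 0--1.
#' @param eta_fb additional learning rate when performance feedback is shown,
#'   0--1.
#' @param delta pro-reminder offset (points) on the subjective indifference
#'   point; positive values shift choices toward reminders independently of
#'   confidence (e.g. effort avoidance).
#' @param sigma_choice choice noise (points), > 0.
#' @param lambda_hind hindsight distortion weight, 0--1: how far recalled
#'   initial confidence drifts toward actual internal accuracy.
#' @param conf_noise report noise s.d. (percentage points) added to every
#'   confidence report, >= 0.
#' @param p_ext_believed believed external accuracy used in the subjective
#'   indifference point (defaults to 1: participants assume reminders work).
#' @param meta_gain multiplier on `eta_fb` when explicit metacognitive
#'   feedback is given (defaults to 1: no extra learning beyond performance
#'   feedback).
#'
#' @return a validated list of class `offload_params`.
#' @examples
#' participant_params(p_int = 0.7, conf0 = 40)
#' @export
participant_params <- function(p_int = 0.65, p_ext = 0.97, conf0 = 50,
                               eta_pred = 0, eta_fb = 0, delta = 0,
                               sigma_choice = 1, lambda_hind = 0,
                               conf_noise = 0, p_ext_believed = 1,
                               meta_gain = 1) {
  p <- list(p_int = p_int, p_ext = p_ext, conf0 = conf0, eta_pred = eta_pred,
            eta_fb = eta_fb, delta = delta, sigma_choice = sigma_choice,
            lambda_hind = lambda_hind, conf_noise = conf_noise,
            p_ext_believed = p_ext_believed, meta_gain = meta_gain)
  chk <- function(name, lo, hi, open_lo = FALSE) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < lo || v > hi || (open_lo && v <= lo)) {
      stop("participant parameter '", name, "' must be in [", lo, ", ", hi,
           "]", if (open_lo) " (exclusive lower bound)", "; got ", v,
           call. = FALSE)
    }
  }
  chk("p_int", 0, 1); chk("p_ext", 0, 1); chk("conf0", 0, 100)
  chk("eta_pred", 0, 1); chk("eta_fb", 0, 1)
  chk("delta", -10, 10)
  chk("sigma_choice", 0, Inf, open_lo = TRUE)
  chk("lambda_hind", 0, 1); chk("conf_noise", 0, 100)
  chk("p_ext_believed", 0, 1, open_lo = TRUE)
  chk("meta_gain", 0, 10)
  structure(p, class = "offload_params")
}

clip01 <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

# Confidence reports come from a 0-100 slider: integer valued, clipped.
report_confidence <- function(conf, noise_sd) {
  round(clip01(conf + stats::rnorm(1L, 0, noise_sd)))
}

#' Subjective indifference point
#'
#' The reminder value at which the modelled participant is indifferent
#' between strategies, given their current confidence: the value equalising
#' expected points under believed accuracies, shifted by the pro-reminder
#' offset: `s = 10 * (conf/100) / p_ext_believed - delta`.
#'
#' @param params an [participant_params()] object.
#' @param conf confidence, percent 0--100.
#' @return points (not clamped to the 2--9 task range).
#' @export
indifference_point <- function(params, conf) {
  TASK_INTERNAL_POINTS * (conf / 100) / params$p_ext_believed - params$delta
}

#' Probability of choosing the reminder strategy
#'
#' Probit choice policy: the probability of choosing external reminders on a
#' trial with reminder value `target_value` is
#' `pnorm((target_value - s) / sigma_choice)` where `s` is the subjective
#' indifference point from [indifference_point()]. The probability increases
#' with value, decreases with confidence, and increases with the
#' pro-reminder offset.
#'
#' @param conf confidence, percent 0--100.
#' @param params an [participant_params()] object.
#' @param target_value reminder value(s) in points (vectorised).
#' @return probability (vector) of choosing the reminder strategy.
#' @examples
#' p <- participant_params(sigma_choice = 1)
#' choice_policy(60, p, 2:9)
#' @export
choice_policy <- function(conf, params, target_value) {
  s <- indifference_point(params, conf)
  stats::pnorm((target_value - s) / params$sigma_choice)
}

#' Simulate the practice-phase metacognitive intervention
#'
#' All groups perform 5 forced-internal practice trials (5 targets each,
#' accuracy Binomial(5, p_int)/5). Depending on the protocol, a confidence
#' prediction is logged before each trial and confidence is updated after it
#' by the error-driven rule `c <- c + eta * (acc - c)` (percent scale),
#' with `eta = eta_pred` when only predictions are made and
#' `eta = eta_pred + meta_gain * eta_fb` (meta_gain applies only under
#' explicit metacognitive feedback) when performance feedback is shown.
#' The control protocol makes no predictions and leaves confidence untouched.
#'
#' Consumes the current RNG stream.
#'
#' @param params an [participant_params()] object.
#' @param protocol a protocol from [protocol_for()].
#' @param accuracies optional numeric vector of 5 practice accuracies in
#'   percent, overriding simulation (used when replaying imported data or in
#'   deterministic checks).
#' @return list with `practice_predictions` (integer percents; length 0 when
#'   no predictions are made), `practice_accuracies` (5 percents), and
#'   `conf_after` (latent confidence after the intervention, unrounded).
#' @export
run_intervention <- function(params, protocol, accuracies = NULL) {
  n <- protocol$n_practice
  if (is.null(accuracies)) {
    accuracies <- 100 * stats::rbinom(n, TASK_N_TARGETS, params$p_int) / TASK_N_TARGETS
  }
  stopifnot(length(accuracies) == n, all(accuracies >= 0 & accuracies <= 100))
  eta <- 0
  if (protocol$makes_prediction) eta <- eta + params$eta_pred
  if (protocol$gives_perf_feedback) {
    gain <- if (protocol$gives_meta_feedback) params$meta_gain else 1
    eta <- eta + gain * params$eta_fb
  }
  eta <- min(eta, 1)
  conf <- params$conf0
  predictions <- integer(0)
  for (t in seq_len(n)) {
    if (protocol$makes_prediction) {
      predictions <- c(predictions, report_confidence(conf, params$conf_noise))
      conf <- clip01(conf + eta * (accuracies[t] - conf))
    }
  }
  list(practice_predictions = predictions,
       practice_accuracies = accuracies,
       conf_after = conf)
}

#' Simulate one participant
#'
#' Runs the practice intervention, logs the pre-task confidence report,
#' simulates the 16 experimental trials (strategy choice via
#' [choice_policy()]; forced trials overwrite mismatching choices; target
#' accuracy Binomial(5, p) under the executed strategy; free trials
#' terminate early and record no accuracy), then logs recalled initial
#' confidence (when the protocol collects it) and the post-task report.
#' Recall is distorted toward actual forced-internal accuracy:
#' `conf_recalled = conf_pre + lambda_hind * (acc_fi - conf_pre) + noise`.
#'
#' Latent confidence is frozen after the pre-task report: the model assumes
#' no further learning during the experimental block.
#'
#' @param params an [participant_params()] object.
#' @param protocol a protocol from [protocol_for()].
#' @param seed optional integer; when given, seeds the RNG so the whole
#'   record (schedule included) is reproducible from it.
#' @param id participant identifier stored in the record.
#' @param schedule optional schedule data.frame; defaults to a fresh draw
#'   from the participant's stream.
#' @return a list of class `offload_record` with fields `id`, `group`,
#'   `params`, `practice_predictions`, `practice_accuracies`, `conf_latent`,
#'   `conf_pre`, `conf_recalled` (NA unless collected), `conf_post`, and
#'   `trials` (the schedule plus `chosen`, `executed`, `overwritten`,
#'   `n_correct`).
#' @examples
#' rec <- simulate_participant(participant_params(), protocol_for("g1_control"), seed = 7)
#' head(rec$trials)
#' @export
simulate_participant <- function(params, protocol, seed = NULL, id = "p1",
                                 schedule = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(schedule)) schedule <- schedule_from_rng()
  intervention <- run_intervention(params, protocol)
  conf <- intervention$conf_after
  conf_pre <- report_confidence(conf, params$conf_noise)

  n <- nrow(schedule)
  p_rem <- choice_policy(conf, params, schedule$target_value)
  chosen <- ifelse(stats::runif(n) < p_rem, "reminder", "internal")
  designated <- ifelse(schedule$designation == "forced_internal", "internal",
                       ifelse(schedule$designation == "forced_external", "reminder", NA))
  executed <- ifelse(schedule$designation == "free", chosen, designated)
  overwritten <- schedule$designation != "free" & chosen != designated
  p_exec <- ifelse(executed == "reminder", params$p_ext, params$p_int)
  n_correct <- ifelse(schedule$early_terminate, NA_integer_,
                      stats::rbinom(n, TASK_N_TARGETS, p_exec))

  trials <- schedule
  trials$chosen <- chosen
  trials$executed <- executed
  trials$overwritten <- overwritten
  trials$n_correct <- as.integer(n_correct)

  conf_recalled <- NA_integer_
  if (protocol$collects_recall) {
    fi <- trials$designation == "forced_internal"
    acc_fi <- 100 * sum(trials$n_correct[fi]) / (sum(fi) * TASK_N_TARGETS)
    conf_recalled <- report_confidence(
      conf_pre + params$lambda_hind * (acc_fi - conf_pre), params$conf_noise)
  }
  conf_post <- report_confidence(conf, params$conf_noise)

  structure(
    list(id = id, group = protocol$group, params = params,
         practice_predictions = intervention$practice_predictions,
         practice_accuracies = intervention$practice_accuracies,
         conf_latent = conf, conf_pre = conf_pre,
         conf_recalled = conf_recalled, conf_post = conf_post,
         trials = trials),
    class = "offload_record")
}

#' Default group parameter distributions
#'
#' The cohort conditions used throughout the package: every group shares the
#' same population distributions (memory ability, initial confidence,
#' pro-reminder offset, noise); the additive intervention effects arise from
#' the protocol flags gating the learning rates. Each entry is a
#' `c(mean, sd)` pair for a clipped-normal draw.
#'
#' Values reflect the regime of online optimal-offloading cohorts: internal
#' accuracy around 66% (s.d. 18), near-ceiling external accuracy, broad and
#' largely underconfident initial confidence (mean 50, s.d. 25), a weak
#' prediction-only learning rate (0.05) against a substantial
#' feedback-driven one (0.25), a mild pro-reminder offset (0.5 points),
#' moderate choice noise (1 point), and a hindsight weight of 0.25.
#'
#' @param experiment `"exp1"` (two groups: control and full intervention) or
#'   `"exp2"` (all four additive groups).
#' @return named list (one element per group) of parameter distribution
#'   specs.
#' @export
default_group_params <- function(experiment = c("exp2", "exp1")) {
  experiment <- match.arg(experiment)
  base <- list(
    p_int = c(0.66, 0.18),
    p_ext = c(0.97, 0.05),
    conf0 = c(50, 25),
    eta_pred = c(0.05, 0.02),
    eta_fb = c(0.25, 0.10),
    delta = c(0.5, 1.0),
    sigma_choice = c(1.0, 0.3),
    lambda_hind = c(0.25, 0.15),
    conf_noise = c(5, 2)
  )
  groups <- if (experiment == "exp1") c("g1_control", "g4_full") else offload_groups()
  stats::setNames(rep(list(base), length(groups)), groups)
}

# Parameter ranges used when drawing individual participants.
PARAM_RANGES <- list(
  p_int = c(0.02, 0.995), p_ext = c(0.5, 1), conf0 = c(0, 100),
  eta_pred = c(0, 1), eta_fb = c(0, 1), delta = c(-5, 5),
  sigma_choice = c(0.2, 5), lambda_hind = c(0, 1), conf_noise = c(0, 30)
)

draw_params <- function(spec) {
  vals <- lapply(names(spec), function(nm) {
    ms <- spec[[nm]]
    r <- PARAM_RANGES[[nm]]
    clip01(stats::rnorm(1L, ms[1], ms[2]), r[1], r[2])
  })
  names(vals) <- names(spec)
  do.call(participant_params, vals)
}

validate_group_params <- function(group_params) {
  if (is.null(names(group_params)) || !all(names(group_params) %in% offload_groups())) {
    stop("group_params must be a named list keyed by group labels (",
         paste(offload_groups(), collapse = ", "), ")", call. = FALSE)
  }
  for (g in names(group_params)) {
    spec <- group_params[[g]]
    if (!all(names(spec) %in% names(PARAM_RANGES))) {
      bad <- setdiff(names(spec), names(PARAM_RANGES))
      stop("unknown parameter(s) in spec for ", g, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    ok <- vapply(spec, function(ms) is.numeric(ms) && length(ms) == 2L &&
                   !anyNA(ms) && ms[2] >= 0, logical(1L))
    if (!all(ok)) {
      stop("each parameter spec must be a numeric c(mean, sd) with sd >= 0 (group ",
           g, ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate a cohort
#'
#' Draws `n_per_group` participants for each group in `group_params`, each
#' with individual parameters drawn from the group's clipped-normal specs.
#' Per-participant seeds are derived deterministically from `master_seed`,
#' so the same seed reproduces the cohort exactly and individual records can
#' be regenerated in isolation.
#'
#' @param n_per_group participants per group (>= 1).
#' @param group_params named list of per-group parameter distribution specs,
#'   e.g. from [default_group_params()].
#' @param master_seed integer master seed.
#' @param collects_recall logical; collect the recalled-confidence judgement
#'   (the four-group design does).
#' @return list of `offload_record` objects.
#' @examples
#' cohort <- simulate_cohort(5, default_group_params("exp1"), master_seed = 1)
#' length(cohort)
#' @export
simulate_cohort <- function(n_per_group, group_params, master_seed,
                            collects_recall = length(group_params) == 4L) {
  stopifnot(is.numeric(n_per_group), n_per_group >= 1)
  validate_group_params(group_params)
  groups <- names(group_params)
  n_total <- as.integer(n_per_group) * length(groups)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  records <- vector("list", n_total)
  k <- 0L
  for (g in groups) {
    protocol <- protocol_for(g, collects_recall = collects_recall)
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      set.seed(seeds[k])
      params <- draw_params(group_params[[g]])
      records[[k]] <- simulate_participant(
        params, protocol, id = sprintf("%s_%03d", g, i))
    }
  }
  records
}
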