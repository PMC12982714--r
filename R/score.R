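#' Forced internal / external accuracy
#'
#' Percent correct pooled over targets within each forced condition (4
#' trials x 5 targets each in the standard design, so forced-internal
#' accuracy has a resolution of 5 percentage points). Pooling is at the
#' target level, which coincides with trial-level means under the fixed
#' 5-target design but stays well-defined if trials are missing.
#'
#' @param trials a participant's trial data.frame (needs `designation` and
#'   `n_correct`).
#' @return named numeric `c(acc_fi, acc_fe)` in percent.
#' @export
compute_accuracies <- function(trials) {
  out <- vapply(c(fi = "forced_internal", fe = "forced_external"), function(d) {
    rows <- trials$designation == d & !is.na(trials$n_correct)
    if (!any(rows)) {
      stop("participant has no scored ", d, " trials; cannot compute accuracies",
           call. = FALSE)
    }
    100 * sum(trials$n_correct[rows]) / (sum(rows) * TASK_N_TARGETS)
  }, numeric(1L))
  c(acc_fi = unname(out["fi"]), acc_fe = unname(out["fe"]))
}

#' Optimal indifference point
#'
#' The reminder value at which an unbiased participant would be indifferent
#' between earning 10 points per target with internal memory or this value
#' with external reminders: `OIP = 10 * ACC_FI / ACC_FE`. Not clamped to the
#' nominal 2--9 task range: out-of-range values are legal and contribute to
#' bias scores.
#'
#' @param acc_fi forced-internal accuracy, percent.
#' @param acc_fe forced-external accuracy, percent (> 0).
#' @return points.
#' @examples
#' compute_oip(60, 100)  # 6: the unbiased worked example
#' @export
compute_oip <- function(acc_fi, acc_fe) {
  if (any(acc_fe <= 0)) stop("OIP undefined for acc_fe <= 0", call. = FALSE)
  TASK_INTERNAL_POINTS * acc_fi / acc_fe
}

# Bounds of the psychometric fit. Location is the task's value range; the
# slope cap keeps the curve identifiable from 16 binary choices over unit-
# spaced values (at 10/point the curve is effectively a step).
AIP_RANGE <- c(2, 9)
AIP_SLOPE_RANGE <- c(0.05, 10)

psy_negll <- function(loc, slope, values, choices) {
  p <- stats::pnorm(slope * (values - loc))
  p <- pmin(1 - 1e-12, pmax(1e-12, p))
  -sum(choices * log(p) + (1 - choices) * log(1 - p))
}

#' Fit the actual indifference point (AIP)
#'
#' Maximum-likelihood fit of a two-parameter cumulative-normal psychometric
#' function `P(reminder | v) = pnorm(slope * (v - location))` to the
#' strategy choices (0 = internal memory, 1 = reminder) across target
#' values, with the location box-constrained to the task's value range
#' 2--9. All 16 choices contribute, including overwritten and
#' early-terminated trials. The AIP is the (bounded) location: the value at
#' which reminder use crosses 50%.
#'
#' All-reminder and all-internal response vectors short-circuit to the
#' respective bound (2 and 9). Optimisation is multi-start L-BFGS-B
#' (locations 2.5/5.5/8.5 crossed with three slopes); ties go to the
#' highest likelihood, then the lowest location.
#'
#' @param values numeric vector of target values (>= 2 distinct).
#' @param choices numeric/logical vector, 1 = reminder chosen.
#' @return list of class `offload_psyfit` with `location`, `slope`,
#'   `bounded_location`, `loglik`, `converged`, `degenerate`
#'   (`"none"`, `"all_reminder"`, `"all_internal"`).
#' @examples
#' sch <- generate_schedule(1)
#' fit_aip(sch$target_value, as.integer(sch$target_value >= 6))
#' @export
fit_aip <- function(values, choices) {
  choices <- as.numeric(choices)
  stopifnot(length(values) == length(choices),
            all(choices %in% c(0, 1)))
  if (length(unique(values)) < 2L) {
    stop("AIP fit needs choices at >= 2 distinct target values", call. = FALSE)
  }
  make_fit <- function(loc, slope, ll, converged, degenerate) {
    structure(list(location = loc, slope = slope,
                   bounded_location = clip01(loc, AIP_RANGE[1], AIP_RANGE[2]),
                   loglik = ll, converged = converged, degenerate = degenerate),
              class = "offload_psyfit")
  }
  if (all(choices == 1)) {
    return(make_fit(AIP_RANGE[1], AIP_SLOPE_RANGE[2], 0, TRUE, "all_reminder"))
  }
  if (all(choices == 0)) {
    return(make_fit(AIP_RANGE[2], AIP_SLOPE_RANGE[2], 0, TRUE, "all_internal"))
  }
  starts <- expand.grid(loc = c(2.5, 5.5, 8.5), slope = c(0.3, 1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(
      par = c(starts$loc[i], starts$slope[i]),
      fn = function(par) psy_negll(par[1], par[2], values, choices),
      method = "L-BFGS-B",
      lower = c(AIP_RANGE[1], AIP_SLOPE_RANGE[1]),
      upper = c(AIP_RANGE[2], AIP_SLOPE_RANGE[2]),
      control = list(factr = 1e4, maxit = 500L))
    better <- is.null(best) || opt$value < best$value - 1e-9 ||
      (abs(opt$value - best$value) <= 1e-9 && opt$par[1] < best$par[1])
    if (better) best <- opt
  }
  make_fit(best$par[1], best$par[2], -best$value,
           best$convergence == 0L, "none")
}

#' Metacognitive hindsight bias
#'
#' Directional distortion of remembered initial confidence toward actual
#' performance: when actual forced-internal accuracy exceeded initial
#' confidence, recalled minus initial confidence; when it fell short,
#' initial minus recalled confidence; zero when accuracy equalled
#' confidence. Positive values mean recall drifted toward how the
#' participant actually performed. Vectorised.
#'
#' @param conf_pre initial confidence report, percent.
#' @param conf_recalled recalled initial confidence, percent.
#' @param acc_fi actual forced-internal accuracy, percent.
#' @return percentage points.
#' @examples
#' compute_hindsight(50, 60, 70)  # +10: remembered as more confident
#' compute_hindsight(50, 40, 30)  # +10: remembered as less confident
#' @export
compute_hindsight <- function(conf_pre, conf_recalled, acc_fi) {
  stopifnot(all(conf_pre >= 0 & conf_pre <= 100, na.rm = TRUE),
            all(conf_recalled >= 0 & conf_recalled <= 100, na.rm = TRUE),
            all(acc_fi >= 0 & acc_fi <= 100, na.rm = TRUE))
  sign(acc_fi - conf_pre) * (conf_recalled - conf_pre)
}

#' Derived measures for one participant
#'
#' Assembles the full score set from a participant record and its
#' psychometric fit: forced accuracies, OIP, AIP, signed and absolute
#' reminder bias (OIP - AIP), confidence reports, signed and absolute
#' metacognitive bias (confidence - ACC_FI, positive = overconfident),
#' hindsight bias (when recall was collected), total reminder choices, and
#' the proportion of trials performed with the chosen strategy.
#'
#' @param record an `offload_record` (or an imported record with the same
#'   fields).
#' @param fit optional `offload_psyfit`; defaults to fitting the record's
#'   choices.
#' @return one-row data.frame (a score set).
#' @export
compute_biases <- function(record, fit = NULL) {
  trials <- record$trials
  acc <- compute_accuracies(trials)
  if (is.null(fit)) {
    fit <- fit_aip(trials$target_value, trials$chosen == "reminder")
  }
  oip <- compute_oip(acc["acc_fi"], acc["acc_fe"])
  aip <- fit$bounded_location
  hb <- if (is.na(record$conf_recalled)) NA_real_ else
    compute_hindsight(record$conf_pre, record$conf_recalled, acc["acc_fi"])
  data.frame(
    id = record$id,
    group = record$group,
    acc_fi = unname(acc["acc_fi"]),
    acc_fe = unname(acc["acc_fe"]),
    oip = unname(oip),
    aip = aip,
    reminder_bias = unname(oip) - aip,
    abs_reminder_bias = abs(unname(oip) - aip),
    conf_pre = record$conf_pre,
    conf_post = record$conf_post,
    conf_recalled = record$conf_recalled,
    meta_bias_pre = record$conf_pre - unname(acc["acc_fi"]),
    meta_bias_post = record$conf_post - unname(acc["acc_fi"]),
    abs_meta_bias_pre = abs(record$conf_pre - unname(acc["acc_fi"])),
    abs_meta_bias_post = abs(record$conf_post - unname(acc["acc_fi"])),
    hindsight_bias = unname(hb),
    total_reminders = sum(trials$chosen == "reminder"),
    prop_chosen_applied = mean(!trials$overwritten),
    aip_converged = fit$converged,
    aip_degenerate = fit$degenerate,
    stringsAsFactors = FALSE
  )
}

#' Score a cohort
#'
#' Applies [compute_biases()] to every record, returning the participant-
#' level scores table.
#'
#' @param records list of participant records.
#' @return data.frame with one row per participant.
#' @examples
#' cohort <- simulate_cohort(4, default_group_params("exp1"), master_seed = 2)
#' scores <- score_cohort(cohort)
#' scores[, c("id", "oip", "aip", "reminder_bias")]
#' @export
score_cohort <- function(records) {
  do.call(rbind, lapply(records, compute_biases))
}
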