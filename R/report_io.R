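# Column registries for the interchange CSVs. Behavioural platforms export
# flat logs, so the trial table is tidy (one row per trial) and the
# participant table one row per participant.
TRIALS_COLUMNS <- c("id", "group", "index", "target_value", "designation",
                    "n_circles", "n_targets", "side_left", "side_top",
                    "side_right", "early_terminate", "chosen", "executed",
                    "overwritten", "n_correct")
PARTICIPANTS_COLUMNS <- c("id", "group", "conf_pre", "conf_recalled",
                          "conf_post",
                          paste0("practice_acc_", 1:5),
                          paste0("practice_pred_", 1:5))

#' Flatten a cohort to tidy data frames
#'
#' @param records list of participant records from [simulate_cohort()].
#' @return `cohort_trials()`: one row per trial; `cohort_participants()`:
#'   one row per participant (practice predictions padded with NA for
#'   groups that make none).
#' @export
cohort_trials <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    cbind(data.frame(id = r$id, group = r$group, stringsAsFactors = FALSE),
          r$trials)
  }))
}

#' @rdname cohort_trials
#' @export
cohort_participants <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    pred <- rep(NA_integer_, 5L)
    if (length(r$practice_predictions)) {
      pred[seq_along(r$practice_predictions)] <- r$practice_predictions
    }
    row <- data.frame(id = r$id, group = r$group,
                      conf_pre = r$conf_pre, conf_recalled = r$conf_recalled,
                      conf_post = r$conf_post, stringsAsFactors = FALSE)
    row[paste0("practice_acc_", 1:5)] <- as.list(r$practice_accuracies)
    row[paste0("practice_pred_", 1:5)] <- as.list(pred)
    row
  }))
}

#' Rebuild participant records from tidy tables
#'
#' Inverse of [cohort_trials()] / [cohort_participants()] for imported or
#' round-tripped data; generative parameters are not recoverable and are
#' left `NULL`.
#'
#' @param trials,participants validated tidy tables.
#' @return list of records suitable for [score_cohort()].
#' @export
records_from_frames <- function(trials, participants) {
  validate_trials(trials)
  validate_participants(participants)
  lapply(seq_len(nrow(participants)), function(i) {
    p <- participants[i, ]
    tr <- trials[trials$id == p$id, setdiff(names(trials), c("id", "group")),
                 drop = FALSE]
    tr <- tr[order(tr$index), , drop = FALSE]
    rownames(tr) <- NULL
    acc <- as.numeric(p[paste0("practice_acc_", 1:5)])
    pred <- as.numeric(p[paste0("practice_pred_", 1:5)])
    structure(
      list(id = p$id, group = p$group, params = NULL,
           practice_predictions = pred[!is.na(pred)],
           practice_accuracies = acc,
           conf_latent = NA_real_, conf_pre = p$conf_pre,
           conf_recalled = p$conf_recalled, conf_post = p$conf_post,
           trials = tr),
      class = "offload_record")
  })
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

check_values <- function(ok, what, df) {
  bad <- which(!ok & !is.na(ok))
  if (length(bad)) {
    stop("invalid ", what, " at row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ...", call. = FALSE)
  }
}

#' Validate interchange tables against the column registry
#'
#' Schema violations name the offending column and rows.
#'
#' @param trials,participants data.frames to validate.
#' @return invisibly `TRUE`.
#' @export
validate_trials <- function(trials) {
  require_columns(trials, TRIALS_COLUMNS, "trials")
  check_values(trials$target_value %in% TASK_VALUES, "target_value", trials)
  check_values(trials$designation %in% c("free", "forced_internal", "forced_external"),
               "designation", trials)
  check_values(trials$chosen %in% c("internal", "reminder"), "chosen", trials)
  check_values(trials$executed %in% c("internal", "reminder"), "executed", trials)
  nc <- trials$n_correct
  check_values(is.na(nc) | (nc >= 0 & nc <= TASK_N_TARGETS), "n_correct", trials)
  check_values(!trials$early_terminate | is.na(nc),
               "n_correct on early-terminated trial", trials)
  invisible(TRUE)
}

#' @rdname validate_trials
#' @export
validate_participants <- function(participants) {
  require_columns(participants, PARTICIPANTS_COLUMNS, "participants")
  for (col in c("conf_pre", "conf_recalled", "conf_post")) {
    v <- participants[[col]]
    check_values(is.na(v) | (v >= 0 & v <= 100), col, participants)
  }
  invisible(TRUE)
}

#' Read / write the interchange CSVs
#'
#' Plain CSVs with the registered column sets, validated on both paths so
#' `write` then `read` is the identity on valid data.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the validated data.frame (readers), or invisibly `path`
#'   (writers).
#' @export
write_trials <- function(x, path) {
  validate_trials(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(x)
  x
}

#' @rdname write_trials
#' @export
write_participants <- function(x, path) {
  validate_participants(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_participants <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_participants(x)
  x
}

#' @rdname write_trials
#' @export
write_scores <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_scores <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles everything that determines a pipeline run: the experiment layout
#' (two-group or four-group additive), per-group sample size, the master
#' seed from which all randomness flows, group parameter distributions, and
#' the exclusion switches. A config plus the package version determines
#' every output.
#'
#' @param experiment `"exp1"` (control vs full intervention, 82/group
#'   default) or `"exp2"` (four additive groups, 104/group default, with
#'   confidence recall).
#' @param n_per_group participants per group; defaults to the design's
#'   planned per-group n.
#' @param master_seed integer master seed.
#' @param group_params per-group parameter specs; defaults to
#'   [default_group_params()].
#' @param mad_scale,mad_threshold exclusion switches, see
#'   [apply_exclusions()].
#' @return list of class `offload_config`.
#' @export
pipeline_config <- function(experiment = c("exp1", "exp2"),
                            n_per_group = NULL, master_seed = 1L,
                            group_params = NULL,
                            mad_scale = 1.4826, mad_threshold = 2.5) {
  experiment <- match.arg(experiment)
  if (is.null(n_per_group)) n_per_group <- if (experiment == "exp1") 82L else 104L
  if (is.null(group_params)) group_params <- default_group_params(experiment)
  validate_group_params(group_params)
  structure(list(experiment = experiment,
                 n_per_group = as.integer(n_per_group),
                 master_seed = as.integer(master_seed),
                 group_params = group_params,
                 mad_scale = mad_scale, mad_threshold = mad_threshold,
                 collects_recall = experiment == "exp2"),
            class = "offload_config")
}

#' Group summary table
#'
#' Means and standard deviations of the derived measures by group, in the
#' layout of the behavioural summary tables (one column pair per group).
#'
#' @param scores participant-level scores.
#' @return data.frame with `measure`, then `<group>_mean` / `<group>_sd`
#'   columns.
#' @export
group_summary <- function(scores) {
  measures <- c("acc_fi", "acc_fe", "conf_pre", "conf_post", "conf_recalled",
                "meta_bias_pre", "meta_bias_post",
                "abs_meta_bias_pre", "abs_meta_bias_post",
                "aip", "oip", "reminder_bias", "abs_reminder_bias",
                "total_reminders", "prop_chosen_applied", "hindsight_bias")
  measures <- intersect(measures, names(scores))
  groups <- unique(scores$group)
  out <- data.frame(measure = measures, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- scores[scores$group == g, measures, drop = FALSE]
    out[[paste0(g, "_mean")]] <- vapply(sub, function(x) mean(x, na.rm = TRUE),
                                        numeric(1L))
    out[[paste0(g, "_sd")]] <- vapply(sub, function(x) stats::sd(x, na.rm = TRUE),
                                      numeric(1L))
  }
  out
}

#' Run the full pipeline
#'
#' Chains simulate, score, exclude, and the experiment's inferential
#' battery. For the two-group layout: mixed Group x Time ANOVAs on signed
#' and absolute metacognitive bias, one-sample reminder-bias tests per
#' group, the one-tailed group comparison of reminder bias, and per-group
#' AIP regressions. For the four-group layout: one-way ANOVAs with linear
#' contrast on the absolute bias measures, the group-1-vs-4 planned
#' comparisons, hindsight tests, and the regressions.
#'
#' @param config an [pipeline_config()] object.
#' @param out_dir optional directory; when given, writes `trials.csv`,
#'   `participants.csv`, `scores.csv`, `exclusions.csv`,
#'   `surviving_scores.csv`, `group_summary.csv`, and `stats.json`.
#' @return list with `config`, `records`, `trials`, `participants`,
#'   `scores`, `exclusions`, `survivors`, `summary`, `stats`, and `log`
#'   (stage counts).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "offload_config"))
  records <- simulate_cohort(config$n_per_group, config$group_params,
                             config$master_seed,
                             collects_recall = config$collects_recall)
  trials <- cohort_trials(records)
  participants <- cohort_participants(records)
  scores <- score_cohort(records)
  excl <- apply_exclusions(scores, trials = trials,
                           mad_scale = config$mad_scale,
                           mad_threshold = config$mad_threshold)
  surv <- excl$survivors
  stats_report <- experiment_stats(surv, config$experiment)
  log <- c(simulated = length(records), scored = nrow(scores),
           excluded = sum(excl$flags$excluded), surviving = nrow(surv))
  bundle <- list(config = config, records = records, trials = trials,
                 participants = participants, scores = scores,
                 exclusions = excl, survivors = surv,
                 summary = group_summary(surv), stats = stats_report,
                 log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    write_participants(participants, file.path(out_dir, "participants.csv"))
    write_scores(scores, file.path(out_dir, "scores.csv"))
    utils::write.csv(excl$flags, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    write_scores(surv, file.path(out_dir, "surviving_scores.csv"))
    utils::write.csv(bundle$summary, file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    write_stats_json(stats_report, file.path(out_dir, "stats.json"))
  }
  bundle
}

#' Inferential battery for a scored, filtered cohort
#'
#' Runs the experiment's planned analyses on surviving scores: for the
#' two-group layout, mixed Group x Time ANOVAs on signed and absolute
#' metacognitive bias, the one-tailed group comparisons, one-sample and
#' between-group reminder-bias tests, and per-group AIP regressions; for
#' the four-group layout, one-way ANOVAs with linear contrast on the bias
#' measures, the planned control-vs-full comparisons, hindsight tests, and
#' the regressions.
#'
#' @param scores surviving participant-level scores.
#' @param experiment `"exp1"` or `"exp2"`.
#' @return named list of `offload_stat` objects and ANOVA tables.
#' @export
experiment_stats <- function(scores, experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") exp1_stats(scores) else exp2_stats(scores)
}

#' Serialise a stats report to JSON
#'
#' @param stats a report from [experiment_stats()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(stats_to_list(stats), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

first_last_groups <- function(scores) {
  groups <- intersect(offload_groups(), unique(scores$group))
  list(control = groups[1], full = groups[length(groups)])
}

exp1_stats <- function(surv) {
  gl <- first_last_groups(surv)
  ctrl <- surv[surv$group == gl$control, ]
  full <- surv[surv$group == gl$full, ]
  conf_avg <- function(s) (s$conf_pre + s$conf_post) / 2
  list(
    meta_bias_anova = mixed_anova_2x2(surv$meta_bias_pre, surv$meta_bias_post,
                                      surv$group),
    abs_meta_bias_anova = mixed_anova_2x2(surv$abs_meta_bias_pre,
                                          surv$abs_meta_bias_post, surv$group),
    meta_bias_pre_group = t_test(ctrl$meta_bias_pre, full$meta_bias_pre,
                                 tails = "one", variance = "welch",
                                 direction = "less"),
    abs_meta_bias_pre_group = t_test(ctrl$abs_meta_bias_pre,
                                     full$abs_meta_bias_pre,
                                     tails = "one", variance = "welch"),
    reminder_bias_onesample = lapply(
      stats::setNames(list(ctrl, full), c(gl$control, gl$full)),
      function(s) t_test(s$reminder_bias, mu = 0, tails = "two")),
    reminder_bias_group = t_test(ctrl$reminder_bias, full$reminder_bias,
                                 tails = "one", variance = "pooled"),
    abs_reminder_bias_group = t_test(ctrl$abs_reminder_bias,
                                     full$abs_reminder_bias,
                                     tails = "one", variance = "welch"),
    regression = lapply(
      stats::setNames(list(ctrl, full), c(gl$control, gl$full)),
      function(s) regression_aip(s$aip, s$oip, conf_avg(s)))
  )
}

exp2_stats <- function(surv) {
  gl <- first_last_groups(surv)
  ctrl <- surv[surv$group == gl$control, ]
  full <- surv[surv$group == gl$full, ]
  conf_avg <- function(s) (s$conf_pre + s$conf_post) / 2
  groups <- intersect(offload_groups(), unique(surv$group))
  list(
    abs_meta_bias_pre_contrast = oneway_linear_contrast(surv$abs_meta_bias_pre,
                                                        surv$group),
    abs_meta_bias_post_contrast = oneway_linear_contrast(surv$abs_meta_bias_post,
                                                         surv$group),
    meta_bias_pre_contrast = oneway_linear_contrast(surv$meta_bias_pre,
                                                    surv$group),
    reminder_bias_contrast = oneway_linear_contrast(surv$reminder_bias,
                                                    surv$group),
    abs_reminder_bias_contrast = oneway_linear_contrast(surv$abs_reminder_bias,
                                                        surv$group),
    abs_meta_bias_pre_g1_g4 = t_test(ctrl$abs_meta_bias_pre,
                                     full$abs_meta_bias_pre,
                                     tails = "one", variance = "welch"),
    abs_reminder_bias_g1_g4 = t_test(ctrl$abs_reminder_bias,
                                     full$abs_reminder_bias,
                                     tails = "one", variance = "welch"),
    hindsight = hindsight_tests(surv$hindsight_bias, surv$group),
    regression = lapply(
      stats::setNames(groups, groups),
      function(g) {
        s <- surv[surv$group == g, ]
        regression_aip(s$aip, s$oip, conf_avg(s))
      })
  )
}

# Recursively convert stat objects to plain lists for JSON serialisation.
stats_to_list <- function(x) {
  if (inherits(x, "offload_stat")) return(unclass(x))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, stats_to_list))
  x
}
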