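#' Per-participant value-choice correlation
#'
#' Pearson correlation between target value and the reminder-choice
#' indicator across a participant's 16 trials; the exclusion cascade flags
#' negative correlations as counter-rational strategy choice. Constant
#' choice vectors (all-internal or all-reminder) have no defined
#' correlation and return `NA`.
#'
#' @param trials tidy trial data.frame with columns `id`, `target_value`,
#'   `chosen`.
#' @return named numeric vector of correlations, one per participant id.
#' @export
choice_value_correlation <- function(trials) {
  vapply(split(trials, trials$id), function(tr) {
    ch <- as.numeric(tr$chosen == "reminder")
    if (stats::sd(ch) == 0 || stats::sd(tr$target_value) == 0) return(NA_real_)
    stats::cor(tr$target_value, ch)
  }, numeric(1L))
}

scaled_mad <- function(x, scale) {
  stats::median(abs(x - stats::median(x))) * scale
}

#' Apply the pre-registered exclusion cascade
#'
#' Sequentially flags participants under six criteria: (a) forced internal
#' accuracy below 10%; (b) forced external accuracy below 70%; (c) negative
#' correlation between target value and reminder choice (counter-rational
#' responding; undefined correlations from constant choice vectors are
#' retained); (d) forced internal accuracy above forced external accuracy;
#' (e) reminder bias more than `mad_threshold` median-absolute-deviation
#' units from the participant's group median; (f) the same rule for the
#' signed pre-task metacognitive bias. Group medians and MADs for (e) and
#' (f) are computed among participants surviving (a)--(d), and the cascade
#' runs in a single pass: a participant flagged at an earlier criterion is
#' counted there only and does not enter later reference distributions.
#'
#' @param scores participant-level scores from [score_cohort()] (needs
#'   `id`, `group`, `acc_fi`, `acc_fe`, `reminder_bias`, `meta_bias_pre`).
#' @param trials tidy trial data.frame (see [choice_value_correlation()]);
#'   or pass precomputed correlations via `value_choice_r`.
#' @param value_choice_r optional named vector of per-participant
#'   value-choice correlations (names = ids), replacing `trials`.
#' @param mad_scale MAD consistency constant; the default 1.4826 makes the
#'   MAD estimate the SD under normality (the convention the 2.5 threshold
#'   comes from). Set to 1 for the raw MAD.
#' @param mad_threshold outlier cut in MAD units.
#' @return list of class `offload_exclusions` with `flags` (one row per
#'   participant: per-criterion logicals, `excluded`, `first_criterion`),
#'   `counts` (named exclusions per criterion), `surviving_ids`,
#'   `survivors` (the filtered scores), and `order_applied`.
#' @export
apply_exclusions <- function(scores, trials = NULL, value_choice_r = NULL,
                             mad_scale = 1.4826, mad_threshold = 2.5) {
  if (is.null(value_choice_r)) {
    if (is.null(trials)) {
      stop("supply either `trials` or precomputed `value_choice_r`",
           call. = FALSE)
    }
    value_choice_r <- choice_value_correlation(trials)
  }
  r <- value_choice_r[match(scores$id, names(value_choice_r))]
  n <- nrow(scores)
  crit <- c("a_low_fi", "b_low_fe", "c_neg_corr", "d_fi_gt_fe",
            "e_rb_outlier", "f_mb_outlier")
  flags <- matrix(FALSE, n, length(crit), dimnames = list(scores$id, crit))
  alive <- rep(TRUE, n)

  mark <- function(which_crit, hit) {
    hit <- alive & hit & !is.na(hit)
    flags[, which_crit] <<- hit
    alive <<- alive & !hit
  }
  mark("a_low_fi", scores$acc_fi < 10)
  mark("b_low_fe", scores$acc_fe < 70)
  mark("c_neg_corr", !is.na(r) & r < 0)
  mark("d_fi_gt_fe", scores$acc_fi > scores$acc_fe)

  # MAD criteria: reference distributions among survivors of (a)-(d)
  ref <- alive
  for (spec in list(c("e_rb_outlier", "reminder_bias"),
                    c("f_mb_outlier", "meta_bias_pre"))) {
    dev <- rep(NA_real_, n)
    for (g in unique(scores$group)) {
      in_ref <- ref & scores$group == g
      if (sum(in_ref) < 3L) {
        warning("group ", g, " has fewer than 3 survivors; MAD criterion ",
                spec[1], " skipped for it", call. = FALSE)
        next
      }
      x <- scores[[spec[2]]]
      med <- stats::median(x[in_ref])
      mad <- scaled_mad(x[in_ref], mad_scale)
      idx <- which(scores$group == g)
      d0 <- abs(x[idx] - med)
      dev[idx] <- ifelse(d0 == 0, 0, d0 / mad)  # zero deviation never flagged
    }
    mark(spec[1], dev > mad_threshold)
  }

  flags_df <- data.frame(id = scores$id, group = scores$group, flags,
                         stringsAsFactors = FALSE, row.names = NULL)
  flags_df$excluded <- !alive
  flags_df$first_criterion <- apply(flags, 1L, function(z) {
    if (any(z)) crit[which(z)[1]] else NA_character_
  })
  structure(
    list(flags = flags_df,
         counts = colSums(flags),
         surviving_ids = scores$id[alive],
         survivors = scores[alive, , drop = FALSE],
         order_applied = crit),
    class = "offload_exclusions")
}

#' @export
print.offload_exclusions <- function(x, ...) {
  cat("Exclusion cascade:", sum(x$flags$excluded), "of", nrow(x$flags),
      "participants excluded\n")
  print(x$counts)
  invisible(x)
}
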