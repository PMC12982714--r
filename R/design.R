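#' Task design constants
#'
#' The value-based offloading task uses 16 trials. Each trial presents 15
#' circles with 5 targets embedded; targets are worth 10 points each when
#' performed from internal memory, or `target_value` (2--9) points each when
#' external reminders are used.
#'
#' @keywords internal
#' @name design-constants
NULL

TASK_N_TRIALS <- 16L
TASK_N_CIRCLES <- 15L
TASK_N_TARGETS <- 5L
TASK_VALUES <- 2:9
TASK_INTERNAL_POINTS <- 10
TASK_SIDES <- c("left", "top", "right")

#' Group labels for the additive intervention design
#'
#' Four groups, each receiving the previous group's intervention components
#' plus one more: g1 is the control (practice only), g2 adds metacognitive
#' predictions, g3 adds performance feedback, g4 adds explicit metacognitive
#' (over/under-confidence) feedback. The two-group design maps its
#' no-feedback group to `g1_control` and its feedback group to `g4_full`.
#'
#' @export
offload_groups <- function() {
  c("g1_control", "g2_prediction", "g3_perf_feedback", "g4_full")
}

#' Intervention protocol for a group
#'
#' Returns the additive component flags for one of the four intervention
#' groups. All groups perform 5 forced-internal practice trials; the flags
#' control whether a confidence prediction is made before each practice
#' trial, whether performance feedback is shown after it, and whether the
#' feedback explicitly labels the prediction as over/under-confident.
#'
#' @param group one of `"g1_control"`, `"g2_prediction"`,
#'   `"g3_perf_feedback"`, `"g4_full"`.
#' @param collects_recall logical; whether the protocol asks participants to
#'   recall their initial confidence after the experimental block (the
#'   four-group replication does, the two-group design does not).
#'
#' @return a list with elements `group`, `n_practice`, `makes_prediction`,
#'   `gives_perf_feedback`, `gives_meta_feedback`, `collects_recall`.
#' @examples
#' protocol_for("g3_perf_feedback")
#' @export
protocol_for <- function(group, collects_recall = FALSE) {
  groups <- offload_groups()
  if (!is.character(group) || length(group) != 1L || !group %in% groups) {
    stop("unknown group label: ", deparse(substitute(group)), " = ",
         paste(group, collapse = ", "),
         "; expected one of ", paste(groups, collapse = ", "), call. = FALSE)
  }
  rank <- match(group, groups)
  list(
    group = group,
    n_practice = 5L,
    makes_prediction = rank >= 2L,
    gives_perf_feedback = rank >= 3L,
    gives_meta_feedback = rank >= 4L,
    collects_recall = isTRUE(collects_recall)
  )
}

#' Draw a target layout for one trial
#'
#' The 5 targets are split across the three non-exit sides of the box: one
#' randomly chosen side receives a single target and the other two receive
#' two each. Consumes the current R random number stream.
#'
#' @return named integer vector over `c("left", "top", "right")` summing to 5.
#' @examples
#' set.seed(1)
#' generate_target_layout()
#' @export
generate_target_layout <- function() {
  single <- sample(TASK_SIDES, 1L)
  counts <- stats::setNames(rep(2L, 3L), TASK_SIDES)
  counts[single] <- 1L
  counts
}

#' Generate a 16-trial offloading schedule
#'
#' Each target value 2--9 appears once (in random order) within trials 1--8
#' and once again (re-randomised) within trials 9--16. Half the values are
#' designated forced-internal and half forced-external, split by parity
#' ({2,4,6,8} vs {3,5,7,9}), with which parity is forced-internal drawn
#' uniformly per participant. The remaining 8 trials are free-choice trials,
#' which terminate early (they contribute strategy choices but no target
#' accuracy data).
#'
#' Draws are consumed from a generator seeded with `seed` in a fixed order:
#' forced parity, then the two block permutations, then one layout per trial.
#'
#' @param seed non-negative integer seed; identical seeds give identical
#'   schedules.
#' @return a data.frame of 16 rows with columns `index`, `target_value`,
#'   `designation` (`free`/`forced_internal`/`forced_external`), `n_circles`,
#'   `n_targets`, `side_left`, `side_top`, `side_right`, `early_terminate`,
#'   with attributes `forced_parity` (`"even_internal"` or `"odd_internal"`)
#'   and `seed`.
#' @examples
#' sch <- generate_schedule(42)
#' table(sch$designation)
#' @export
generate_schedule <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0, seed == round(seed))
  set.seed(as.integer(seed))
  sch <- schedule_from_rng()
  attr(sch, "seed") <- as.integer(seed)
  sch
}

# Schedule draw consuming the current RNG stream (used by the participant
# simulator so that one per-participant seed governs the whole record).
schedule_from_rng <- function() {
  parity <- sample(c("even_internal", "odd_internal"), 1L)
  forced_internal_values <- if (parity == "even_internal") c(2L, 4L, 6L, 8L) else c(3L, 5L, 7L, 9L)
  values <- c(sample(TASK_VALUES), sample(TASK_VALUES))
  designation <- rep("free", TASK_N_TRIALS)
  # each value appears once per block; its forced designation applies to one
  # of its two presentations, chosen so that blocks stay value-complete and
  # forced trials are spread across the session
  for (v in TASK_VALUES) {
    idx <- which(values == v)
    forced_at <- sample(idx, 1L)
    designation[forced_at] <-
      if (v %in% forced_internal_values) "forced_internal" else "forced_external"
  }
  layouts <- t(vapply(seq_len(TASK_N_TRIALS), function(i) generate_target_layout(),
                      integer(3L)))
  sch <- data.frame(
    index = seq_len(TASK_N_TRIALS),
    target_value = values,
    designation = designation,
    n_circles = TASK_N_CIRCLES,
    n_targets = TASK_N_TARGETS,
    side_left = layouts[, "left"],
    side_top = layouts[, "top"],
    side_right = layouts[, "right"],
    early_terminate = designation == "free",
    stringsAsFactors = FALSE
  )
  attr(sch, "forced_parity") <- parity
  sch
}

#' Validate a schedule against the task design invariants
#'
#' Checks trial count, the twice-each value multiset, block completeness,
#' the 4 + 4 forced designation split by value parity, and layout sums.
#' Used by the data-import path and internally by tests.
#'
#' @param schedule a schedule data.frame as from [generate_schedule()].
#' @return invisibly `TRUE`; stops with a diagnostic on violation.
#' @export
validate_schedule <- function(schedule) {
  if (nrow(schedule) != TASK_N_TRIALS) {
    stop("schedule must have ", TASK_N_TRIALS, " trials, got ", nrow(schedule))
  }
  v <- schedule$target_value
  if (!identical(sort(v), rep(TASK_VALUES, each = 2L))) {
    stop("target values must be 2-9 each exactly twice")
  }
  if (!setequal(v[1:8], TASK_VALUES) || !setequal(v[9:16], TASK_VALUES)) {
    stop("each block of 8 trials must contain each target value once")
  }
  des <- schedule$designation
  fi <- v[des == "forced_internal"]
  fe <- v[des == "forced_external"]
  if (length(fi) != 4L || length(fe) != 4L) {
    stop("schedule must have exactly 4 forced_internal and 4 forced_external trials")
  }
  ok_parity <- (setequal(fi, c(2, 4, 6, 8)) && setequal(fe, c(3, 5, 7, 9))) ||
    (setequal(fi, c(3, 5, 7, 9)) && setequal(fe, c(2, 4, 6, 8)))
  if (!ok_parity) stop("forced designations must partition target values by parity")
  lay <- as.matrix(schedule[, c("side_left", "side_top", "side_right")])
  if (any(rowSums(lay) != TASK_N_TARGETS)) stop("target layouts must sum to 5")
  if (!all(apply(lay, 1L, function(r) setequal(r, c(1L, 2L, 2L))))) {
    stop("each layout must have one side with 1 target and two sides with 2")
  }
  if (!identical(schedule$early_terminate, des == "free")) {
    stop("early_terminate must hold exactly on free trials")
  }
  invisible(TRUE)
}
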