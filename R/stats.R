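#' @title Statistical results
#' @description Constructor for the common result shape returned by the
#'   inferential functions: statistic, degrees of freedom, p value,
#'   tailedness, labelled effect size, and the underlying estimate.
#' @keywords internal
stat_result <- function(statistic, df, p, tails, effect_size = NA_real_,
                        effect_type = NA_character_, estimate = NA_real_,
                        method = NA_character_) {
  structure(list(statistic = statistic, df = df, p = p, tails = tails,
                 effect_size = effect_size, effect_type = effect_type,
                 estimate = estimate, method = method),
            class = "offload_stat")
}

#' @export
print.offload_stat <- function(x, ...) {
  dfs <- paste(signif(x$df, 5), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s-tailed)\n",
              x$method, x$statistic, dfs, x$p, x$tails))
  if (!is.na(x$effect_size)) {
    cat(sprintf("  %s = %.4g, estimate = %.4g\n",
                x$effect_type, x$effect_size, x$estimate))
  }
  invisible(x)
}

pooled_sd <- function(x, y) {
  sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
         (length(x) + length(y) - 2))
}

#' Cohen's d
#'
#' Two-sample d uses the pooled standard deviation regardless of which
#' variance flavour the t test uses; one-sample d is `(mean - mu) / sd`.
#'
#' @param x,y numeric samples (`y = NULL` for the one-sample form).
#' @param mu null value for the one-sample form.
#' @return numeric effect size.
#' @export
cohens_d <- function(x, y = NULL, mu = 0) {
  if (is.null(y)) return((mean(x) - mu) / stats::sd(x))
  (mean(x) - mean(y)) / pooled_sd(x, y)
}

#' t tests with the reporting conventions of the offloading analyses
#'
#' Wraps [stats::t.test()] (Welch or pooled-variance two-sample, or
#' one-sample against `mu`) and attaches Cohen's d. `tails = "one"` reports
#' the one-tailed p for the direction given by `direction` (`"greater"`
#' means H1: mean(x) > mean(y), or mean(x) > mu in the one-sample form).
#'
#' @param x,y numeric samples; omit `y` for a one-sample test.
#' @param mu null value (one-sample form).
#' @param tails `"two"` or `"one"`.
#' @param variance `"welch"` (Satterthwaite df) or `"pooled"`
#'   (df = n1 + n2 - 2); ignored for one-sample tests.
#' @param direction hypothesised direction for one-tailed tests.
#' @return an `offload_stat`.
#' @examples
#' set.seed(1)
#' t_test(rnorm(20, 1), rnorm(20), tails = "one", variance = "pooled")
#' @export
t_test <- function(x, y = NULL, mu = 0, tails = c("two", "one"),
                   variance = c("welch", "pooled"),
                   direction = c("greater", "less")) {
  tails <- match.arg(tails)
  variance <- match.arg(variance)
  direction <- match.arg(direction)
  x <- x[!is.na(x)]
  if (!is.null(y)) y <- y[!is.na(y)]
  if (length(x) < 2L || (!is.null(y) && length(y) < 2L)) {
    stop("t test needs >= 2 observations per sample", call. = FALSE)
  }
  alternative <- if (tails == "two") "two.sided" else direction
  if (is.null(y)) {
    if (stats::sd(x) == 0 && mean(x) == mu) {
      # no variance and no deviation: no evidence either way
      return(stat_result(0, length(x) - 1, if (tails == "two") 1 else 0.5,
                         tails, 0, "cohens_d", 0, "one-sample t"))
    }
    tt <- stats::t.test(x, mu = mu, alternative = alternative)
    d <- cohens_d(x, mu = mu)
    est <- mean(x) - mu
    method <- "one-sample t"
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      stop("t undefined: zero variance in both samples with equal means",
           call. = FALSE)
    }
    tt <- stats::t.test(x, y, alternative = alternative,
                        var.equal = variance == "pooled")
    d <- cohens_d(x, y)
    est <- mean(x) - mean(y)
    method <- paste0(if (variance == "pooled") "pooled" else "Welch",
                     " two-sample t")
  }
  stat_result(unname(tt$statistic), unname(tt$parameter), tt$p.value, tails,
              d, "cohens_d", est, method)
}

#' Two-sample t test from summary statistics
#'
#' Reproduces the group comparisons computable from printed summary tables
#' (means, SDs, and ns). Pooled or Welch variance; Cohen's d from the pooled
#' SD.
#'
#' @param m1,s1,n1 mean, SD, n of the first group.
#' @param m2,s2,n2 mean, SD, n of the second group.
#' @inheritParams t_test
#' @return an `offload_stat`.
#' @examples
#' t_test_summary(1.60, 2.27, 82, 0.81, 2.27, 82, tails = "one", variance = "pooled")
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2, tails = c("two", "one"),
                           variance = c("welch", "pooled"),
                           direction = c("greater", "less")) {
  tails <- match.arg(tails)
  variance <- match.arg(variance)
  direction <- match.arg(direction)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (variance == "pooled") {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  p2 <- 2 * stats::pt(-abs(tstat), df)
  p <- if (tails == "two") p2 else {
    sgn <- if (direction == "greater") tstat else -tstat
    stats::pt(sgn, df, lower.tail = FALSE)
  }
  stat_result(tstat, df, p, tails, (m1 - m2) / sqrt(sp2), "cohens_d",
              m1 - m2, paste0(variance, " two-sample t (summary)"))
}

partial_eta_sq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Mixed 2 x (pre, post) ANOVA
#'
#' Mixed ANOVA with a between-subject Group factor and a two-level
#' within-subject Time factor (pre-task, post-task), computed from the
#' subject-means / difference-scores decomposition. With unequal group
#' sizes the Time effect tests the unweighted mean of group mean changes
#' (Type-III-style); with balanced groups this coincides with the
#' sequential decomposition. Reports F, df, p, and partial eta squared per
#' effect.
#'
#' @param dv_pre,dv_post paired pre/post observations, one per participant.
#' @param group between-subject factor (any number of levels >= 2).
#' @return data.frame with rows `Group`, `Time`, `Group:Time`.
#' @export
mixed_anova_2x2 <- function(dv_pre, dv_post, group) {
  if (anyNA(dv_pre) || anyNA(dv_post)) {
    stop("mixed ANOVA requires complete pre/post pairs", call. = FALSE)
  }
  stopifnot(length(dv_pre) == length(dv_post),
            length(group) == length(dv_pre))
  group <- factor(group)
  G <- nlevels(group)
  if (G < 2L) stop("need >= 2 groups", call. = FALSE)
  N <- length(dv_pre)
  m <- (dv_pre + dv_post) / 2
  d <- dv_post - dv_pre
  ng <- tabulate(group, nbins = G)
  if (any(ng == 0L)) stop("empty group in mixed ANOVA", call. = FALSE)
  mg <- tapply(m, group, mean)
  dg <- tapply(d, group, mean)

  # between stratum (subject means, factor Group)
  ss_group <- 2 * sum(ng * (mg - mean(m))^2)
  ss_eb <- 2 * sum((m - mg[group])^2)
  df_b <- c(G - 1, N - G)
  f_group <- (ss_group / df_b[1]) / (ss_eb / df_b[2])

  # within stratum (difference scores, effects Time and Group:Time)
  safe_f <- function(num, den) {
    if (den == 0) return(if (num == 0) 0 else Inf)  # degenerate: constant d
    num / den
  }
  ss_ew <- sum((d - dg[group])^2) / 2
  ms_ew <- ss_ew / (N - G)
  s2d <- sum((d - dg[group])^2) / (N - G)
  u <- mean(dg)  # unweighted mean change
  f_time <- safe_f(u^2, s2d * sum(1 / ng) / G^2)
  ss_int <- sum(ng * (dg - mean(d))^2) / 2
  f_int <- safe_f(ss_int / (G - 1), ms_ew)

  out <- data.frame(
    effect = c("Group", "Time", "Group:Time"),
    F = c(f_group, f_time, f_int),
    df1 = c(G - 1, 1, G - 1),
    df2 = c(N - G, N - G, N - G),
    stringsAsFactors = FALSE
  )
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$pes <- partial_eta_sq(out$F, out$df1, out$df2)
  out
}

#' One-way ANOVA with linear contrast
#'
#' Omnibus one-way ANOVA across ordered groups plus the one-degree-of-
#' freedom linear trend contrast with equally spaced weights (for four
#' groups, proportional to (-3, -1, 1, 3)). Unequal group sizes are handled
#' through `sum(w^2 / n)` in the contrast standard error.
#'
#' @param dv numeric outcome.
#' @param group ordered group labels (>= 2 non-empty levels).
#' @return data.frame with rows `Group` (omnibus) and `Linear`.
#' @export
oneway_linear_contrast <- function(dv, group) {
  keep <- !is.na(dv)
  dv <- dv[keep]
  group <- group[keep]
  if (!is.factor(group)) group <- factor(group)
  G <- nlevels(group)
  ng <- tabulate(group, nbins = G)
  if (any(ng == 0L)) stop("empty group in one-way ANOVA", call. = FALSE)
  N <- length(dv)
  fit <- stats::lm(dv ~ group)
  an <- stats::anova(fit)
  f_omni <- an$`F value`[1]
  mse <- an$`Mean Sq`[2]

  w <- seq_len(G) - (G + 1) / 2
  w <- w / min(abs(w))  # (-3, -1, 1, 3) for G = 4
  means <- tapply(dv, group, mean)
  est <- sum(w * means)
  f_lin <- est^2 / (mse * sum(w^2 / ng))

  out <- data.frame(
    effect = c("Group", "Linear"),
    F = c(f_omni, f_lin),
    df1 = c(G - 1, 1),
    df2 = N - G,
    stringsAsFactors = FALSE
  )
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$pes <- partial_eta_sq(out$F, out$df1, out$df2)
  out$estimate <- c(NA_real_, est)
  out
}

#' Regression of actual on optimal indifference point and confidence
#'
#' Ordinary least squares predicting AIP from OIP and a confidence rating
#' (typically the average of pre- and post-task reports): does confidence
#' explain strategy variance beyond what objective performance implies?
#' Returns the result for the confidence coefficient.
#'
#' @param aip,oip,confidence numeric vectors of equal length (n > 3).
#' @return an `offload_stat` for the confidence coefficient (t with n - 3
#'   df, two-tailed p).
#' @export
regression_aip <- function(aip, oip, confidence) {
  keep <- stats::complete.cases(aip, oip, confidence)
  aip <- aip[keep]; oip <- oip[keep]; confidence <- confidence[keep]
  n <- length(aip)
  if (n <= 3L) stop("regression needs n > 3", call. = FALSE)
  r <- stats::cor(oip, confidence)
  if (!is.finite(r) || abs(r) >= 1 - 1e-12) {
    stop("predictors are collinear; confidence coefficient not identifiable",
         call. = FALSE)
  }
  fit <- stats::lm(aip ~ oip + confidence)
  cf <- summary(fit)$coefficients["confidence", ]
  stat_result(unname(cf["t value"]), n - 3, unname(cf["Pr(>|t|)"]), "two",
              estimate = unname(cf["Estimate"]),
              method = "OLS confidence coefficient")
}

two_sample_t_power <- function(n, d, alpha, tails) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- if (tails == "one") stats::qt(1 - alpha, df) else stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Per-group sample size for a two-sample t test
#'
#' Smallest per-group n at which an independent-samples t test attains the
#' requested power, using the noncentral-t power function with
#' `ncp = d * sqrt(n / 2)` and `df = 2n - 2` (for two-tailed tests the
#' small probability of rejection in the wrong tail is ignored, matching
#' standard power software).
#'
#' @param d true standardised effect size (> 0).
#' @param alpha significance level.
#' @param power target power (alpha < power < 1).
#' @param tails `"one"` or `"two"`.
#' @param n_max search cap; requested power beyond it is rejected.
#' @return integer per-group n.
#' @examples
#' power_n_per_group(0.39, 0.05, 0.80, tails = "one")  # 82
#' @export
power_n_per_group <- function(d, alpha = 0.05, power = 0.80,
                              tails = c("one", "two"), n_max = 1e6) {
  tails <- match.arg(tails)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  lo <- 2L
  if (two_sample_t_power(n_max, d, alpha, tails) < power) {
    stop("requested power unattainable within n_max = ", n_max, call. = FALSE)
  }
  hi <- lo
  while (two_sample_t_power(hi, d, alpha, tails) < power) hi <- min(hi * 2L, n_max)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (two_sample_t_power(mid, d, alpha, tails) >= power) hi <- mid else lo <- mid + 1L
  }
  as.integer(lo)
}

#' Hindsight-bias tests
#'
#' Pooled two-tailed one-sample t of the hindsight-bias scores against
#' zero, per-group one-sample ts, and the one-way group ANOVA. Missing
#' scores are dropped.
#'
#' @param hb hindsight-bias scores (percentage points).
#' @param group group labels.
#' @return list with `pooled` (`offload_stat`), `per_group` (named list of
#'   `offload_stat`), and `anova` (data.frame from
#'   [oneway_linear_contrast()]).
#' @export
hindsight_tests <- function(hb, group) {
  keep <- !is.na(hb)
  hb <- hb[keep]
  group <- factor(group[keep])
  list(
    pooled = t_test(hb, mu = 0, tails = "two"),
    per_group = lapply(stats::setNames(levels(group), levels(group)),
                       function(g) t_test(hb[group == g], mu = 0, tails = "two")),
    anova = oneway_linear_contrast(hb, group)
  )
}
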