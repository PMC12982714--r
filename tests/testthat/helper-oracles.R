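# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force grids, base aov/lm, and hand algebra.

# Grid-search MLE for the bounded psychometric fit: location 2..9 in 0.01
# steps, log-spaced slope grid over the same admissible slope range.
grid_fit_aip <- function(values, choices, loc_step = 0.01) {
  locs <- seq(2, 9, by = loc_step)
  slopes <- exp(seq(log(0.05), log(10), length.out = 160))
  best_ll <- -Inf
  best_loc <- NA_real_
  for (s in slopes) {
    # 16 x n_loc matrix of success probabilities
    p <- stats::pnorm(s * outer(values, locs, "-"))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)  # args ordered to keep the dim
    ll <- colSums(choices * log(p) + (1 - choices) * log(1 - p))
    i <- which.max(ll)
    if (ll[i] > best_ll + 1e-12) {
      best_ll <- ll[i]
      best_loc <- locs[i]
    }
  }
  list(location = best_loc, loglik = best_ll)
}

# Random response vectors over the standard 16-trial value layout: a blend
# of probit responders (varying location/slope) and pure-noise responders.
random_response_vector <- function() {
  values <- c(sample(2:9), sample(2:9))
  if (stats::runif(1) < 0.2) {
    choices <- stats::rbinom(16, 1, stats::runif(1, 0.2, 0.8))
  } else {
    loc <- stats::runif(1, 1, 10)
    slope <- stats::runif(1, 0.2, 5)
    choices <- stats::rbinom(16, 1, stats::pnorm(slope * (values - loc)))
  }
  list(values = values, choices = choices)
}

# Satterthwaite df evaluated directly from its defining expression.
welch_df_oracle <- function(x, y) {
  v1 <- stats::var(x) / length(x)
  v2 <- stats::var(y) / length(y)
  (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
}

# Mixed-ANOVA oracle for balanced designs: base aov with an Error stratum.
aov_mixed_oracle <- function(pre, post, group) {
  n <- length(pre)
  long <- data.frame(
    dv = c(pre, post),
    time = factor(rep(c("pre", "post"), each = n), levels = c("pre", "post")),
    group = factor(rep(group, 2)),
    id = factor(rep(seq_len(n), 2))
  )
  fit <- summary(stats::aov(dv ~ group * time + Error(id / time), data = long))
  btw <- fit[["Error: id"]][[1]]
  wth <- fit[["Error: id:time"]][[1]]
  list(
    F_group = btw["group", "F value"],
    F_time = wth["time", "F value"],
    F_int = wth["group:time", "F value"],
    pes_group = btw["group", "Sum Sq"] /
      (btw["group", "Sum Sq"] + btw["Residuals", "Sum Sq"]),
    pes_time = wth["time", "Sum Sq"] /
      (wth["time", "Sum Sq"] + wth["Residuals", "Sum Sq"]),
    pes_int = wth["group:time", "Sum Sq"] /
      (wth["group:time", "Sum Sq"] + wth["Residuals", "Sum Sq"])
  )
}

# Two-predictor OLS through the normal equations.
ols_oracle <- function(y, x1, x2) {
  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  list(beta = unname(drop(beta)), t = unname(drop(beta) / se))
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-12)
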