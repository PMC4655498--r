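# Random-effects pooling of relative risks from 2x2 trial tables.
# DerSimonian-Laird on the log-RR scale with a Wald 95% CI -- the
# conventional reading of "random effects" for binary risk ratios.

#' Construct a table of 2x2 trial counts
#'
#' @param trial_id Character vector of trial labels.
#' @param events_treated,n_treated Events and arm size in the treated arm.
#' @param events_control,n_control Events and arm size in the control arm.
#' @return A `data.frame` of class `trial_table` with one row per trial.
#' @export
trial_table <- function(trial_id, events_treated, n_treated,
                        events_control, n_control) {
  df <- data.frame(trial_id = as.character(trial_id),
                   events_treated = as.numeric(events_treated),
                   n_treated = as.numeric(n_treated),
                   events_control = as.numeric(events_control),
                   n_control = as.numeric(n_control),
                   stringsAsFactors = FALSE)
  validate_trials(df)
}

validate_trials <- function(df) {
  need <- c("trial_id", "events_treated", "n_treated", "events_control", "n_control")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("trial table lacks column(s): %s", paste(missing, collapse = ", "))
  num <- df[need[-1]]
  if (any(!vapply(num, is.numeric, logical(1)))) stopf("trial counts must be numeric")
  if (any(unlist(num) < 0)) stopf("trial counts must be non-negative")
  if (any(df$n_treated <= 0) || any(df$n_control <= 0)) stopf("no arm may have n = 0")
  if (any(df$events_treated > df$n_treated) || any(df$events_control > df$n_control)) {
    stopf("events exceed arm size in a trial")
  }
  class(df) <- unique(c("trial_table", class(df)))
  df
}

#' Read trial tables from CSV
#'
#' Expects columns `trial_id,events_treated,n_treated,events_control,n_control`.
#'
#' @param path CSV file path.
#' @return A validated `trial_table` data frame.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("trial file not found: %s", path)
  validate_trials(read.csv(path, stringsAsFactors = FALSE))
}

#' Pool relative risks across trials (DerSimonian-Laird random effects)
#'
#' Per-trial log relative risks `log((a/n1)/(c/n2))` with variances
#' `1/a - 1/n1 + 1/c - 1/n2` are combined by inverse-variance weighting;
#' Cochran's Q yields the method-of-moments between-trial variance
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, the weights are
#' re-formed as `1/(v_i + tau^2)`, and a Wald 95% confidence interval is
#' exponentiated back to the ratio scale.
#'
#' Trials with a zero cell in one arm receive the Haldane-Anscombe
#' continuity correction (`continuity` added to all four cells of that
#' trial only); their ids are recorded in the result. Trials with zero
#' events in both arms carry no information about a risk ratio and are
#' excluded with a warning; if every trial is double-zero the pooled effect
#' is undefined and an error is signalled.
#'
#' @param trials A `trial_table` (or data frame with the same columns).
#' @param continuity Continuity correction added to all four cells of a
#'   trial with a single-arm zero cell (default 0.5).
#' @return An object of class `pooled_rr`: list with `point`, `low`, `high`
#'   (ratio scale), `tau_squared`, `q_statistic`, `k`, `log_point`,
#'   `se_log`, `continuity_trials`, `dropped_trials`.
#' @examples
#' tt <- trial_table("t1", 10, 100, 20, 100)
#' pool_random_effects(tt)  # point 0.5, single-trial Wald CI, tau^2 = 0
#' @export
pool_random_effects <- function(trials, continuity = 0.5) {
  trials <- validate_trials(as.data.frame(trials))
  if (nrow(trials) < 1L) stopf("at least one trial is required")
  if (!is_scalar_number(continuity) || continuity <= 0) {
    stopf("continuity must be a small positive constant")
  }

  double_zero <- trials$events_treated == 0 & trials$events_control == 0
  if (all(double_zero)) {
    stopf("undefined effect: zero events in both arms of every trial")
  }
  dropped <- trials$trial_id[double_zero]
  if (length(dropped)) {
    warnf("excluding %d double-zero trial(s) from pooling: %s",
          length(dropped), paste(dropped, collapse = ", "))
    trials <- trials[!double_zero, , drop = FALSE]
  }

  zero_cell <- trials$events_treated == 0 | trials$events_control == 0
  corrected <- trials$trial_id[zero_cell]
  a <- trials$events_treated + ifelse(zero_cell, continuity, 0)
  n1 <- trials$n_treated + ifelse(zero_cell, 2 * continuity, 0)
  c_ <- trials$events_control + ifelse(zero_cell, continuity, 0)
  n2 <- trials$n_control + ifelse(zero_cell, 2 * continuity, 0)

  yi <- log((a / n1) / (c_ / n2))
  vi <- 1 / a - 1 / n1 + 1 / c_ - 1 / n2

  k <- length(yi)
  w <- 1 / vi
  mu_fe <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_fe)^2)
  tau2 <- if (k > 1L) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0

  w_star <- 1 / (vi + tau2)
  mu <- sum(w_star * yi) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  z <- qnorm(0.975)

  structure(
    list(point = exp(mu),
         low = exp(mu - z * se),
         high = exp(mu + z * se),
         tau_squared = tau2,
         q_statistic = q,
         k = k,
         log_point = mu,
         se_log = se,
         continuity_trials = corrected,
         dropped_trials = dropped),
    class = "pooled_rr")
}

#' @export
print.pooled_rr <- function(x, ...) {
  cat(sprintf("Pooled RR %.4f (95%% CI %.4f to %.4f)\n", x$point, x$low, x$high))
  cat(sprintf("  k = %d trials, Q = %.4f, tau^2 = %.6f\n", x$k, x$q_statistic, x$tau_squared))
  if (length(x$continuity_trials)) {
    cat("  continuity correction applied to:", paste(x$continuity_trials, collapse = ", "), "\n")
  }
  if (length(x$dropped_trials)) {
    cat("  double-zero trials excluded:", paste(x$dropped_trials, collapse = ", "), "\n")
  }
  invisible(x)
}
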