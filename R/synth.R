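# Synthetic data with the statistical structure the analysis assumes:
# trial-level 2x2 tables for meta-analysis parameter recovery, and
# person-level Bernoulli cohorts as a stochastic oracle for the
# deterministic expectation engine.

#' Generate synthetic 2x2 trial tables under a random-effects model
#'
#' Each trial draws a log relative risk from
#' `Normal(log(true_rr), tau_squared)` (the standard log-normal
#' between-trial heterogeneity model), sets the treated-arm risk to
#' `control_risk * exp(theta)` clipped to \[0, 1\], and draws binomial
#' event counts in both arms. Deterministic given `seed`.
#'
#' @param true_rr True underlying relative risk (> 0).
#' @param tau_squared Between-trial variance of the log relative risk
#'   (>= 0).
#' @param k_trials Number of trials.
#' @param n_per_arm Participants per arm.
#' @param control_risk Control-arm event probability.
#' @param seed Integer seed.
#' @return A [trial_table()] with `k_trials` rows.
#' @export
generate_trials <- function(true_rr, tau_squared = 0, k_trials = 10,
                            n_per_arm = 1000, control_risk = 0.16, seed = 1) {
  if (!is_scalar_number(true_rr) || true_rr <= 0) stopf("true_rr must be > 0")
  if (!is_scalar_number(tau_squared) || tau_squared < 0) stopf("tau_squared must be >= 0")
  if (!is_scalar_number(k_trials) || k_trials < 1) stopf("k_trials must be >= 1")
  if (!is_scalar_number(n_per_arm) || n_per_arm < 1) stopf("n_per_arm must be >= 1")
  if (!is_scalar_number(control_risk) || control_risk <= 0 || control_risk >= 1) {
    stopf("control_risk must lie in (0, 1)")
  }
  set.seed(seed)
  theta <- rnorm(k_trials, mean = log(true_rr), sd = sqrt(tau_squared))
  risk_treated_raw <- control_risk * exp(theta)
  risk_treated <- pmin(pmax(risk_treated_raw, 0), 1)
  if (mean(risk_treated_raw != risk_treated) > 0.10) {
    warnf("spec near boundary: treated risk clipped in more than 10%% of trials")
  }
  trial_table(trial_id = sprintf("synthetic_%02d", seq_len(k_trials)),
              events_treated = rbinom(k_trials, n_per_arm, risk_treated),
              n_treated = rep(n_per_arm, k_trials),
              events_control = rbinom(k_trials, n_per_arm, control_risk),
              n_control = rep(n_per_arm, k_trials))
}

#' Simulate person-level cohorts as an oracle for the expectation engine
#'
#' Each replicate draws, for every outcome and setting, a binomial count
#' of events among that setting's births with success probability
#' `baseline rate x RR` (each birth an independent Bernoulli trial per
#' outcome, outcomes independent of one another). Replicate means converge
#' to [evaluate_strategy()]'s expected counts at rate `1/sqrt(replicates)`.
#' Deterministic given `seed`.
#'
#' @param strategy A [strategy()].
#' @param cohort_size Births per replicate; `cohort_size * fraction` must
#'   be a whole number for each setting.
#' @param mix A [setting_mix()].
#' @param evidence An [evidence_set()].
#' @param rr_bound Relative-risk bound.
#' @param n_replicates Number of replicated cohorts.
#' @param seed Integer seed.
#' @return Data frame with columns `outcome`, `mean`, `se` (standard
#'   error of the mean across replicates), plus attributes `n_replicates`
#'   and `expected` (the deterministic counts).
#' @export
simulate_cohort <- function(strategy, cohort_size = 1000, mix = setting_mix(),
                            evidence = tuncalp_evidence(), rr_bound = "point",
                            n_replicates = 200, seed = 1) {
  stopifnot(inherits(strategy, "strategy"), inherits(mix, "setting_mix"),
            inherits(evidence, "evidence_set"))
  if (!is_scalar_number(n_replicates) || n_replicates < 1) {
    stopf("n_replicates must be >= 1")
  }
  n_h <- cohort_size * mix$hospital
  n_c <- cohort_size * mix$community
  if (abs(n_h - round(n_h)) > 1e-9 || abs(n_c - round(n_c)) > 1e-9) {
    stopf("invalid parameter: cohort_size x setting fraction must be integral")
  }
  n_h <- as.integer(round(n_h)); n_c <- as.integer(round(n_c))
  rr_bound <- match_bound(rr_bound)

  probs <- lapply(setNames(outcome_ids(), outcome_ids()), function(oc) {
    cell_h <- resolve_cell(strategy$hospital, oc, evidence, rr_bound)
    cell_c <- resolve_cell(strategy$community, oc, evidence, rr_bound)
    p <- c(hospital = cell_h$baseline_rate * cell_h$rr,
           community = cell_c$baseline_rate * cell_c$rr)
    if (any(p > 1)) {
      stopf("probability overflow: rate x RR exceeds 1 for outcome '%s'", oc)
    }
    p
  })

  set.seed(seed)
  rows <- lapply(outcome_ids(), function(oc) {
    p <- probs[[oc]]
    counts <- rbinom(n_replicates, n_h, p[["hospital"]]) +
      rbinom(n_replicates, n_c, p[["community"]])
    data.frame(outcome = oc, mean = mean(counts),
               se = if (n_replicates > 1) sd(counts) / sqrt(n_replicates) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  expected <- evaluate_strategy(strategy, cohort_size, mix, evidence, rr_bound)
  structure(out, n_replicates = n_replicates, expected = expected$total,
            class = c("cohort_simulation", "data.frame"))
}
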