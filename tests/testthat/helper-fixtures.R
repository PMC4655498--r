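# Shared fixtures, built in code at test time.

# A cohort_result with prescribed counts, for exercising the cost engine
# in isolation from the cohort engine.
make_cohort_result <- function(hospital = rep(0, 6), community = rep(0, 6),
                               cohort_size = 1000, mix = setting_mix()) {
  df <- data.frame(outcome = outcome_ids(), hospital = hospital,
                   community = community, total = hospital + community,
                   stringsAsFactors = FALSE)
  structure(df, class = c("cohort_result", "data.frame"),
            cohort_size = cohort_size, mix = mix,
            strategy = strategy("none", "none"),
            evidence_source = "fixture", rr_bound = "point")
}

# Fixed three-trial 2x2 set used against the hand-computed
# DerSimonian-Laird oracle (moderate heterogeneity, no zero cells).
dl_fixture_trials <- function() {
  trial_table(trial_id = c("alpha", "beta", "gamma"),
              events_treated = c(12, 30, 9),
              n_treated = c(120, 240, 95),
              events_control = c(20, 38, 20),
              n_control = c(115, 250, 100))
}

# A tiny complete evidence set for edge-case rates (zero baselines,
# near-boundary probabilities).
make_edge_evidence <- function(placebo_pph = 0, placebo_rest = 0.5,
                               rr_pph = 1, rr_rest = 1.5) {
  outcomes <- outcome_ids()
  rates <- lapply(outcomes, function(oc) {
    list(point = if (oc == "pph") placebo_pph else placebo_rest)
  })
  names(rates) <- outcomes
  rrs <- lapply(outcomes, function(oc) {
    list(point = if (oc == "pph") rr_pph else rr_rest)
  })
  names(rrs) <- outcomes
  evidence_set("edge_case",
               baseline_rates = list(placebo = rates, oxytocin = rates),
               relative_risks = list(misoprostol_vs_placebo = rrs,
                                     misoprostol_vs_oxytocin = rrs))
}
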