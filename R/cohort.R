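# Deterministic cohort engine: expected event counts per outcome for a
# prophylaxis strategy over a hospital/community setting mix, and
# incremental outcomes between two strategies. Computation stays unrounded
# throughout; integers appear only in reports.

#' Hospital/community setting mix
#'
#' @param hospital Fraction of births in the hospital/health-centre setting.
#' @param community Fraction in the community setting; defaults to the
#'   complement. The base case is 0.4/0.6.
#' @return A `setting_mix` object.
#' @export
setting_mix <- function(hospital = 0.4, community = 1 - hospital) {
  if (!is_scalar_number(hospital) || !is_scalar_number(community) ||
      hospital < 0 || hospital > 1 || community < 0 || community > 1) {
    stopf("invalid parameter: setting fractions must lie in [0, 1]")
  }
  if (abs(hospital + community - 1) > 1e-12) {
    stopf("invalid parameter: setting fractions must sum to 1")
  }
  structure(list(hospital = hospital, community = community), class = "setting_mix")
}

prophylaxis_options <- function() c("oxytocin", "misoprostol", "none")

#' Prophylaxis strategy per setting
#'
#' @param hospital,community Prophylaxis used in each setting: one of
#'   `"oxytocin"`, `"misoprostol"`, `"none"`.
#' @return A `strategy` object.
#' @export
strategy <- function(hospital, community) {
  hospital <- match.arg(hospital, prophylaxis_options())
  community <- match.arg(community, prophylaxis_options())
  structure(list(hospital = hospital, community = community), class = "strategy")
}

#' @export
format.strategy <- function(x, ...) paste0(x$hospital, "/", x$community)

#' @export
print.strategy <- function(x, ...) {
  cat("<strategy>", format(x), "(hospital/community)\n")
  invisible(x)
}

#' An intervention/comparator pair sharing one cohort
#'
#' @param intervention,comparator [strategy()] objects.
#' @param cohort_size Number of births (default 1000).
#' @param mix [setting_mix()] (default 40% hospital / 60% community).
#' @param evidence_source Label of the evidence source (default
#'   `"tuncalp2012"`).
#' @param rr_bound Relative-risk bound used for both arms: `"point"`,
#'   `"low"` or `"high"`.
#' @return A `strategy_pair` object.
#' @export
strategy_pair <- function(intervention, comparator, cohort_size = 1000,
                          mix = setting_mix(), evidence_source = "tuncalp2012",
                          rr_bound = "point") {
  stopifnot(inherits(intervention, "strategy"), inherits(comparator, "strategy"),
            inherits(mix, "setting_mix"))
  if (!is_scalar_number(cohort_size) || cohort_size < 1) {
    stopf("invalid parameter: cohort_size must be >= 1")
  }
  structure(list(intervention = intervention, comparator = comparator,
                 cohort_size = cohort_size, mix = mix,
                 evidence_source = evidence_source,
                 rr_bound = match_bound(rr_bound)),
            class = "strategy_pair")
}

#' Expected number of events
#'
#' The model's elementary arithmetic: births x baseline rate x relative
#' risk. No clamping is applied; a value exceeding the number of births
#' (mathematically possible for a large relative risk on a high baseline)
#' raises a warning.
#'
#' @param n_births Non-negative number of births.
#' @param baseline_rate Baseline event proportion in \[0, 1\].
#' @param rr Positive relative risk.
#' @return Unrounded expected count.
#' @examples
#' expected_events(1000, 0.16, 1.0)   # 160
#' expected_events(600, 0.16, 0.77)   # 73.92
#' @export
expected_events <- function(n_births, baseline_rate, rr) {
  if (!is_scalar_number(n_births) || n_births < 0 ||
      !is_scalar_number(baseline_rate) || baseline_rate < 0 || baseline_rate > 1 ||
      !is_scalar_number(rr) || rr <= 0) {
    stopf("invalid parameter: need n_births >= 0, baseline_rate in [0,1], rr > 0")
  }
  out <- n_births * baseline_rate * rr
  if (out > n_births) {
    warnf("expected events (%.2f) exceed births (%.0f): rate x RR > 1", out, n_births)
  }
  out
}

#' Resolve the baseline rate and relative risk for a prophylaxis option
#'
#' Maps a prophylaxis choice to the (baseline rate, relative risk) pair the
#' engine multiplies: no treatment uses the placebo rate with RR 1;
#' oxytocin uses the oxytocin rate with RR 1 (it is its own baseline
#' context); misoprostol is anchored to the placebo baseline times the
#' misoprostol-vs-placebo relative risk in both settings.
#'
#' @param prophylaxis `"oxytocin"`, `"misoprostol"` or `"none"`.
#' @param outcome One of [outcome_ids()].
#' @param evidence An [evidence_set()].
#' @param rr_bound Bound of the relative risk to apply (baseline rates
#'   always use the point estimate).
#' @return List with `baseline_rate` and `rr`.
#' @export
resolve_cell <- function(prophylaxis, outcome, evidence, rr_bound = "point") {
  prophylaxis <- match.arg(prophylaxis, prophylaxis_options())
  switch(prophylaxis,
    none = list(baseline_rate = get_rate(evidence, "placebo", outcome), rr = 1.0),
    oxytocin = list(baseline_rate = get_rate(evidence, "oxytocin", outcome), rr = 1.0),
    misoprostol = list(
      baseline_rate = get_rate(evidence, "placebo", outcome),
      rr = get_rr(evidence, "misoprostol_vs_placebo", outcome, rr_bound)))
}

#' Expected event counts for one strategy over the setting mix
#'
#' For each outcome, the hospital count is
#' `cohort_size x hospital_fraction x baseline x RR` for the hospital
#' prophylaxis, the community count analogous, and the total their
#' unrounded sum. Outcomes are marginal frequencies computed independently
#' (a woman may contribute to several).
#'
#' @inheritParams resolve_cell
#' @param strategy A [strategy()].
#' @param cohort_size Number of births.
#' @param mix A [setting_mix()].
#' @return A `cohort_result`: data frame with columns `outcome`,
#'   `hospital`, `community`, `total`, carrying the evaluation settings as
#'   attributes.
#' @examples
#' ev <- tuncalp_evidence()
#' res <- evaluate_strategy(strategy("oxytocin", "none"), 1000, setting_mix(0.4), ev)
#' res$total[res$outcome == "pph"]  # 145.6
#' @export
evaluate_strategy <- function(strategy, cohort_size = 1000, mix = setting_mix(),
                              evidence = tuncalp_evidence(), rr_bound = "point") {
  stopifnot(inherits(strategy, "strategy"), inherits(mix, "setting_mix"),
            inherits(evidence, "evidence_set"))
  if (!is_scalar_number(cohort_size) || cohort_size < 0) {
    stopf("invalid parameter: cohort_size must be non-negative")
  }
  rr_bound <- match_bound(rr_bound)
  n_h <- cohort_size * mix$hospital
  n_c <- cohort_size * mix$community
  rows <- lapply(outcome_ids(), function(oc) {
    cell_h <- resolve_cell(strategy$hospital, oc, evidence, rr_bound)
    cell_c <- resolve_cell(strategy$community, oc, evidence, rr_bound)
    h <- expected_events(n_h, cell_h$baseline_rate, cell_h$rr)
    cc <- expected_events(n_c, cell_c$baseline_rate, cell_c$rr)
    data.frame(outcome = oc, hospital = h, community = cc, total = h + cc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cohort_result", "data.frame"),
            strategy = strategy, cohort_size = cohort_size, mix = mix,
            evidence_source = evidence$source_label, rr_bound = rr_bound)
}

same_evaluation_frame <- function(a, b) {
  isTRUE(all.equal(attr(a, "cohort_size"), attr(b, "cohort_size"))) &&
    isTRUE(all.equal(unclass(attr(a, "mix")), unclass(attr(b, "mix"))))
}

#' Incremental outcomes between two strategies
#'
#' Differences (intervention minus comparator) are taken on the unrounded
#' expected counts; the reported integer is the rounded unrounded
#' difference (half away from zero), never a difference of rounded values.
#' Negative increments denote events prevented by the intervention.
#'
#' @param intervention,comparator `cohort_result` objects from
#'   [evaluate_strategy()] under the same cohort size and mix.
#' @return Data frame with columns `outcome`, `unrounded`, `reported`.
#' @export
incremental_outcomes <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "cohort_result"), inherits(comparator, "cohort_result"))
  if (!same_evaluation_frame(intervention, comparator)) {
    stopf("incomparable results: cohort size or setting mix differ")
  }
  diff <- intervention$total - comparator$total
  data.frame(outcome = intervention$outcome,
             unrounded = diff,
             reported = round_half_away(diff),
             stringsAsFactors = FALSE)
}
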