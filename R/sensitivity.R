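# One-way (univariate) sensitivity analyses and the hospital/community
# mix sweep. Each row is produced by the same engines as the base case,
# differing only in the single substituted parameter.

#' Define a one-way substitution
#'
#' Exactly one parameter is varied per substitution:
#' \describe{
#'   \item{`rr_bound`}{use the `"low"`/`"high"` confidence limit of the
#'     relative risks instead of the point estimate.}
#'   \item{`baseline_source`}{swap in another evidence source (its placebo
#'     rates and misoprostol-vs-placebo RRs together), e.g.
#'     `"hundley2013"`; cells the source does not print fall back to the
#'     base evidence.}
#'   \item{`drug_cost_bound`}{reprice both drugs at their `"low"`/`"high"`
#'     bound everywhere.}
#'   \item{`treatment_cost_multiplier`}{scale the PPH treatment cost of
#'     both arms (e.g. 0.5 or 2).}
#'   \item{`stay_costs_override`}{replace the overnight prices; value is
#'     `list(health_centre =, hospital =)`.}
#'   \item{`mix`}{replace the setting mix; value is a [setting_mix()].}
#' }
#'
#' @param target One of the six targets above.
#' @param value The replacement value.
#' @param label Optional row label; a default is derived from the target.
#' @return A `substitution` object.
#' @export
substitution <- function(target, value, label = NULL) {
  target <- match.arg(target, c("rr_bound", "baseline_source", "drug_cost_bound",
                                "treatment_cost_multiplier", "stay_costs_override",
                                "mix"))
  if (is.null(label)) {
    label <- switch(target,
      rr_bound = sprintf("%s bound of RR", value),
      baseline_source = sprintf("evidence source %s", value),
      drug_cost_bound = sprintf("%s cost of drugs", value),
      treatment_cost_multiplier = sprintf("%.0f%% treatment cost", 100 * value),
      stay_costs_override = sprintf("stay costs $%s/$%s per night",
                                    value$health_centre, value$hospital),
      mix = sprintf("%.0f/%.0f %% hospital/community",
                    100 * value$hospital, 100 * value$community))
  }
  structure(list(target = target, value = value, label = label),
            class = "substitution")
}

apply_substitution <- function(config, sub) {
  stopifnot(inherits(config, "model_config"), inherits(sub, "substitution"))
  switch(sub$target,
    rr_bound = {
      config$pair$rr_bound <- match_bound(sub$value)
    },
    baseline_source = {
      config$evidence <- merge_evidence(evidence_by_label(sub$value), config$evidence)
    },
    drug_cost_bound = {
      config$costs <- reprice_drugs(config$costs, sub$value)
    },
    treatment_cost_multiplier = {
      if (!is_scalar_number(sub$value) || sub$value < 0) {
        stopf("unsupported substitution: multiplier must be non-negative")
      }
      config$treatment_cost_multiplier <- sub$value
    },
    stay_costs_override = {
      config$costs <- override_stay_costs(config$costs, sub$value$health_centre,
                                          sub$value$hospital)
    },
    mix = {
      stopifnot(inherits(sub$value, "setting_mix"))
      config$pair$mix <- sub$value
    },
    stopf("unsupported substitution: %s", sub$target))
  config
}

sensitivity_row <- function(label, comparison) {
  inc <- comparison$increments
  row <- as.data.frame(as.list(setNames(inc$reported, inc$outcome)))
  cbind(data.frame(label = label, stringsAsFactors = FALSE),
        row,
        data.frame(incremental_total_cost = comparison$incremental_cost$reported[["total"]],
                   incremental_total_cost_raw = comparison$incremental_cost$total))
}

#' Run one one-way sensitivity analysis
#'
#' Clones the full configuration, applies the single substitution, and
#' recomputes incremental outcomes and costs through the cohort and cost
#' engines. Every non-substituted parameter is carried over unchanged.
#'
#' @param config The base [model_config()].
#' @param sub A [substitution()].
#' @return One-row data frame: `label`, reported incremental count per
#'   outcome, `incremental_total_cost` (whole dollars) and its unrounded
#'   `_raw` companion.
#' @export
one_way <- function(config, sub) {
  sensitivity_row(sub$label, run_model(apply_substitution(config, sub)))
}

#' Run a full one-way sensitivity plan
#'
#' @param config The base [model_config()].
#' @param subs List of [substitution()] objects (may be empty).
#' @param include_base Prepend the base-case row (default `TRUE`).
#' @return Data frame with one row per substitution (plus the base case).
#' @export
sensitivity_table <- function(config, subs = list(), include_base = TRUE) {
  rows <- list()
  if (include_base) rows <- list(sensitivity_row("Base case", run_model(config)))
  rows <- c(rows, lapply(subs, function(s) one_way(config, s)))
  do.call(rbind, rows)
}

#' Sweep the hospital/community mix
#'
#' Recomputes the comparison at each supplied mix. The default grid covers
#' 0/100 through 100/0 in steps of 20 percentage points.
#'
#' @param config The base [model_config()].
#' @param mixes List of [setting_mix()] objects.
#' @return Data frame with one row per mix, as in [one_way()].
#' @export
mix_sweep <- function(config,
                      mixes = lapply(seq(0, 1, by = 0.2), setting_mix)) {
  rows <- lapply(mixes, function(m) one_way(config, substitution("mix", m)))
  do.call(rbind, rows)
}
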