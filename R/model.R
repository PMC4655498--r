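# Full model configuration and the comparison runner that ties the cohort
# and cost engines together into the reported layout.

#' Assemble a full model configuration
#'
#' Bundles everything one comparison needs: the strategy pair, the
#' evidence in effect, unit costs, dosing, the treatment recipe, cost
#' bound and a treatment-cost multiplier. Defaults reproduce the base
#' case: 1000 births, 40/60 hospital/community, primary evidence source,
#' point estimates.
#'
#' @param pair A [strategy_pair()].
#' @param evidence An [evidence_set()]; defaults to the pair's
#'   `evidence_source` label resolved via [evidence_by_label()].
#' @param costs A [unit_cost_table()].
#' @param doses A [dose_schedule()].
#' @param recipe A [treatment_recipe()].
#' @param cost_bound Unit-cost bound used everywhere (`"point"`, `"low"`,
#'   `"high"`).
#' @param treatment_cost_multiplier Scalar applied to the PPH treatment
#'   cost of both arms (sensitivity hook; default 1).
#' @return A `model_config` object.
#' @export
model_config <- function(pair,
                         evidence = evidence_by_label(pair$evidence_source),
                         costs = default_costs(),
                         doses = dose_schedule(),
                         recipe = treatment_recipe(),
                         cost_bound = "point",
                         treatment_cost_multiplier = 1) {
  stopifnot(inherits(pair, "strategy_pair"), inherits(evidence, "evidence_set"),
            inherits(costs, "unit_cost_table"), inherits(doses, "dose_schedule"),
            inherits(recipe, "treatment_recipe"))
  if (!is_scalar_number(treatment_cost_multiplier) || treatment_cost_multiplier < 0) {
    stopf("invalid parameter: treatment_cost_multiplier must be non-negative")
  }
  structure(list(pair = pair, evidence = evidence, costs = costs, doses = doses,
                 recipe = recipe, cost_bound = match_bound(cost_bound),
                 treatment_cost_multiplier = treatment_cost_multiplier),
            class = "model_config")
}

#' The base-case configuration
#'
#' Oxytocin in hospital / misoprostol in community versus oxytocin in
#' hospital / no treatment in community, 1000 births, 40/60 mix, primary
#' evidence, point estimates.
#'
#' @param ... Overrides passed on to [model_config()].
#' @return A `model_config`.
#' @export
base_case_config <- function(...) {
  pair <- strategy_pair(strategy("oxytocin", "misoprostol"),
                        strategy("oxytocin", "none"))
  model_config(pair, ...)
}

arm_costs <- function(strat, result, config) {
  drug <- prophylaxis_cost(strat, config$pair$cohort_size, config$pair$mix,
                           config$costs, config$doses, config$cost_bound)
  treat <- config$treatment_cost_multiplier *
    treatment_cost(result, config$recipe, config$costs, config$cost_bound)
  cost_breakdown(drug, treat)
}

#' Run a comparison under a model configuration
#'
#' Evaluates both strategies with the cohort engine, costs each arm, and
#' returns scenario columns, incremental outcomes and incremental costs,
#' all unrounded with reported integers alongside.
#'
#' @param config A [model_config()].
#' @return A `cca_comparison`: list with `intervention`/`comparator`
#'   cohort results, `increments` (from [incremental_outcomes()]),
#'   `intervention_cost`/`comparator_cost` breakdowns,
#'   `incremental_cost` (from [total_and_incremental_cost()]) and the
#'   `config` it was run under.
#' @export
run_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  pair <- config$pair
  int_res <- evaluate_strategy(pair$intervention, pair$cohort_size, pair$mix,
                               config$evidence, pair$rr_bound)
  comp_res <- evaluate_strategy(pair$comparator, pair$cohort_size, pair$mix,
                                config$evidence, pair$rr_bound)
  int_cost <- arm_costs(pair$intervention, int_res, config)
  comp_cost <- arm_costs(pair$comparator, comp_res, config)
  structure(
    list(intervention = int_res,
         comparator = comp_res,
         increments = incremental_outcomes(int_res, comp_res),
         intervention_cost = int_cost,
         comparator_cost = comp_cost,
         incremental_cost = total_and_incremental_cost(int_cost, comp_cost),
         config = config),
    class = "cca_comparison")
}

#' @export
print.cca_comparison <- function(x, ...) {
  cat("Cost-consequences comparison:",
      format(x$config$pair$intervention), "vs",
      format(x$config$pair$comparator), "\n")
  print(render_comparison(x), row.names = FALSE)
  invisible(x)
}
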