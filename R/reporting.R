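# Configuration loading/validation and rendering of the three result
# layouts (base-case comparison, one-way sensitivity, mix sweep) to CSV
# and human-readable tables. Reported integers always sit next to the
# unrounded engine values (`_raw` columns) for auditability.

config_defaults <- function() {
  list(cohort_size = 1000,
       mix = list(hospital = 0.4, community = 0.6),
       evidence_source = "tuncalp2012",
       rr_bound = "point",
       cost_bound = "point",
       treatment_cost_multiplier = 1)
}

#' Load and validate a model configuration file
#'
#' Reads a YAML or JSON scenario file, applies defaults (cohort 1000, mix
#' 0.4/0.6, primary evidence source, point bounds) and validates every
#' field before any computation; violations name the offending key. The
#' minimal valid file names only the two strategies:
#'
#' ```yaml
#' intervention: {hospital: oxytocin, community: misoprostol}
#' comparator:   {hospital: oxytocin, community: none}
#' ```
#'
#' Optional keys: `cohort_size`, `mix: {hospital, community}`,
#' `evidence_source` or `evidence_file`, `cost_file`, `rr_bound`,
#' `cost_bound`, `treatment_cost_multiplier`, and `recipe`/`doses` blocks
#' whose entries override [treatment_recipe()] / [dose_schedule()]
#' arguments.
#'
#' @param path Path to the configuration file.
#' @return A validated [model_config()].
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(raw)) stopf("config must be a mapping of keys to values")
  known <- c("intervention", "comparator", "cohort_size", "mix",
             "evidence_source", "evidence_file", "cost_file", "rr_bound",
             "cost_bound", "treatment_cost_multiplier", "recipe", "doses")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stopf("config key not recognised: %s", paste(unknown, collapse = ", "))
  raw <- modifyList(config_defaults(), raw)

  parse_strategy <- function(key) {
    s <- raw[[key]]
    if (is.null(s) || is.null(s$hospital) || is.null(s$community)) {
      stopf("config key '%s' must name hospital and community prophylaxis", key)
    }
    if (!all(c(s$hospital, s$community) %in% prophylaxis_options())) {
      stopf("config key '%s': prophylaxis must be one of %s", key,
            paste(prophylaxis_options(), collapse = ", "))
    }
    strategy(s$hospital, s$community)
  }
  intervention <- parse_strategy("intervention")
  comparator <- parse_strategy("comparator")

  if (is.null(raw$mix$hospital)) stopf("config key 'mix' must give a hospital fraction")
  mix <- tryCatch(
    setting_mix(raw$mix$hospital,
                if (is.null(raw$mix$community)) 1 - raw$mix$hospital else raw$mix$community),
    error = function(e) stopf("config key 'mix': %s", conditionMessage(e)))
  if (!is_scalar_number(raw$cohort_size) || raw$cohort_size < 1) {
    stopf("config key 'cohort_size' must be a positive number")
  }
  for (key in c("rr_bound", "cost_bound")) {
    if (!raw[[key]] %in% c("point", "low", "high")) {
      stopf("config key '%s' must be point, low or high", key)
    }
  }
  evidence <- if (!is.null(raw$evidence_file)) {
    read_evidence(raw$evidence_file)
  } else {
    evidence_by_label(raw$evidence_source)
  }
  costs <- if (!is.null(raw$cost_file)) read_costs(raw$cost_file) else default_costs()
  recipe <- tryCatch(do.call(treatment_recipe, as.list(raw$recipe)),
                     error = function(e) stopf("config key 'recipe': %s", conditionMessage(e)))
  doses <- tryCatch(do.call(dose_schedule, as.list(raw$doses)),
                    error = function(e) stopf("config key 'doses': %s", conditionMessage(e)))

  pair <- strategy_pair(intervention, comparator, raw$cohort_size, mix,
                        evidence_source = evidence$source_label,
                        rr_bound = raw$rr_bound)
  model_config(pair, evidence = evidence, costs = costs, doses = doses,
               recipe = recipe, cost_bound = raw$cost_bound,
               treatment_cost_multiplier = raw$treatment_cost_multiplier)
}

#' Render a comparison in the reported table layout
#'
#' One row per outcome plus the three cost rows; reported integers (counts)
#' and whole dollars (costs) in the main columns, unrounded engine values
#' in the `_raw` columns. Negative increments denote reductions under the
#' intervention.
#'
#' @param comparison A `cca_comparison` from [run_model()].
#' @return Data frame with columns `row`, `intervention`, `comparator`,
#'   `increment` and their `_raw` companions.
#' @export
render_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "cca_comparison"))
  int_tot <- comparison$intervention$total
  comp_tot <- comparison$comparator$total
  inc <- comparison$increments
  ic <- comparison$incremental_cost
  icost <- comparison$intervention_cost
  ccost <- comparison$comparator_cost
  raw_int <- c(int_tot, icost$prophylaxis_drug_cost, icost$pph_treatment_cost, icost$total)
  raw_comp <- c(comp_tot, ccost$prophylaxis_drug_cost, ccost$pph_treatment_cost, ccost$total)
  raw_incr <- c(inc$unrounded, ic$drug, ic$treatment, ic$total)
  data.frame(
    row = c(unname(outcome_labels()[inc$outcome]),
            "Drugs for prevention", "Treatment of PPH", "Total cost"),
    intervention = round_half_away(raw_int),
    comparator = round_half_away(raw_comp),
    increment = round_half_away(raw_incr),
    intervention_raw = raw_int,
    comparator_raw = raw_comp,
    increment_raw = raw_incr,
    stringsAsFactors = FALSE)
}

#' Write a result table to CSV
#'
#' Plain UTF-8 CSV with a header row; numeric columns are written with
#' full double precision so that reading the file back reproduces the
#' unrounded values exactly. No currency symbols or separators are
#' emitted.
#'
#' @param df A result data frame ([render_comparison()],
#'   [sensitivity_table()], [mix_sweep()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
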