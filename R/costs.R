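# Cost engine: prophylaxis drug costs and a configurable per-case PPH
# treatment cascade (treatment bundle, referral transport, inpatient
# stays, additional uterotonics, transfusion). Unit costs are 2012 US$.

cost_items <- function() {
  c("oxytocin_10iu", "misoprostol_200ug", "iv_fluids", "infusion_set",
    "blood_unit", "blood_giving_set", "transport_per_km",
    "overnight_health_centre", "overnight_hospital", "syringe")
}

#' Unit-cost table
#'
#' Ten unit costs with point/low/high bounds (2012 US$). The default table
#' is shipped with the package ([default_costs()]); bounds for non-drug
#' items are half/double the point estimate, drug bounds span the listed
#' supplier price range.
#'
#' @param costs Named list: item -> list(point, low, high), covering every
#'   item in the model (oxytocin_10iu, misoprostol_200ug, iv_fluids,
#'   infusion_set, blood_unit, blood_giving_set, transport_per_km,
#'   overnight_health_centre, overnight_hospital, syringe).
#' @return A `unit_cost_table` object.
#' @export
unit_cost_table <- function(costs) {
  missing <- setdiff(cost_items(), names(costs))
  if (length(missing)) stopf("cost table lacks item(s): %s", paste(missing, collapse = ", "))
  out <- lapply(setNames(cost_items(), cost_items()), function(item) {
    est <- as_estimate(costs[[item]], "cost item", item)
    if (any(est <= 0, na.rm = TRUE)) stopf("invalid cost for %s: values must be > 0", item)
    if (!is.na(est[["low"]]) && !is.na(est[["high"]]) &&
        !(est[["low"]] <= est[["point"]] && est[["point"]] <= est[["high"]])) {
      stopf("invalid cost for %s: need low <= point <= high", item)
    }
    est
  })
  structure(out, class = "unit_cost_table")
}

#' Packaged default unit costs
#' @return A [unit_cost_table()] with the shipped 2012 US$ prices.
#' @export
default_costs <- function() read_costs(evidence_file("unit_costs.yaml"))

#' Read a unit-cost table from YAML or JSON
#' @param path File with one `point/low/high` entry per cost item.
#' @return A [unit_cost_table()].
#' @export
read_costs <- function(path) {
  if (!file.exists(path)) stopf("cost file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  unit_cost_table(raw)
}

#' Look up a unit cost
#' @param costs A [unit_cost_table()].
#' @param item A cost item name.
#' @param bound `"point"`, `"low"` or `"high"`.
#' @return The unit cost in model currency.
#' @export
cost_value <- function(costs, item, bound = "point") {
  stopifnot(inherits(costs, "unit_cost_table"))
  if (!item %in% names(costs)) stopf("unknown cost item: %s", item)
  costs[[item]][[match_bound(bound)]]
}

#' Reprice the drug items at a bound
#'
#' Returns a cost table whose oxytocin and misoprostol point estimates are
#' replaced by their `bound` values, leaving all other items unchanged.
#' This implements the "lower/higher cost of drugs" sensitivity analysis:
#' the drug price changes wherever the drug appears, in prophylaxis and in
#' the treatment bundle alike.
#'
#' @inheritParams cost_value
#' @return A [unit_cost_table()].
#' @export
reprice_drugs <- function(costs, bound) {
  stopifnot(inherits(costs, "unit_cost_table"))
  bound <- match_bound(bound)
  for (item in c("oxytocin_10iu", "misoprostol_200ug")) {
    costs[[item]][["point"]] <- costs[[item]][[bound]]
  }
  costs
}

#' Override the overnight-stay unit costs
#' @inheritParams cost_value
#' @param health_centre,hospital Replacement per-night prices.
#' @return A [unit_cost_table()].
#' @export
override_stay_costs <- function(costs, health_centre, hospital) {
  stopifnot(inherits(costs, "unit_cost_table"))
  if (!is_scalar_number(health_centre) || health_centre <= 0 ||
      !is_scalar_number(hospital) || hospital <= 0) {
    stopf("invalid stay-cost override: prices must be positive")
  }
  costs[["overnight_health_centre"]][] <- health_centre
  costs[["overnight_hospital"]][] <- hospital
  costs
}

#' Prophylaxis dosing schedule
#'
#' @param misoprostol_tablets_per_dose Tablets of 200 ug per prophylactic
#'   dose (default 3, i.e. 600 ug).
#' @param include_syringe_in_prophylaxis Whether a syringe is costed with
#'   each prophylactic oxytocin dose (default `FALSE`).
#' @param oxytocin_units_label Display label for the oxytocin dose.
#' @return A `dose_schedule` object.
#' @export
dose_schedule <- function(misoprostol_tablets_per_dose = 3,
                          include_syringe_in_prophylaxis = FALSE,
                          oxytocin_units_label = "10 iU") {
  if (!is_scalar_number(misoprostol_tablets_per_dose) ||
      misoprostol_tablets_per_dose < 1 ||
      misoprostol_tablets_per_dose != round(misoprostol_tablets_per_dose)) {
    stopf("invalid parameter: misoprostol_tablets_per_dose must be a positive integer")
  }
  structure(list(misoprostol_tablets_per_dose = misoprostol_tablets_per_dose,
                 include_syringe_in_prophylaxis = isTRUE(include_syringe_in_prophylaxis),
                 oxytocin_units_label = oxytocin_units_label),
            class = "dose_schedule")
}

#' Per-case PPH treatment recipe
#'
#' Encodes the clinical-management cascade behind the treatment cost: every
#' PPH case receives a treatment bundle (therapeutic oxytocin + syringe +
#' IV fluids + infusion set); hospital-origin cases add an inpatient stay
#' (a fraction requiring a number of nights); community-origin cases start
#' at a health post, are all referred (half to a health centre, half
#' directly to hospital) with an emergency-transport leg, and health-centre
#' cases are half referred onward to hospital with a second transport leg.
#' Additional-uterotonic cases are costed as oxytocin + syringe;
#' transfusions as blood units + giving set. Severe PPH carries no extra
#' cost by default (`severe_pph_extra_cost` is a per-case hook).
#'
#' @param hospital_stay_fraction,hospital_stay_nights Fraction of
#'   hospital-treated cases admitted and nights per admission (defaults
#'   0.5 and 7).
#' @param health_centre_stay_fraction,health_centre_stay_nights As above
#'   for health-centre-treated cases (defaults 0.5 and 2).
#' @param health_post_referral_fraction Fraction of community (health-post)
#'   cases referred onward (default 1).
#' @param referral_split_health_centre Of referred community cases, the
#'   fraction sent to a health centre rather than directly to hospital
#'   (default 0.5).
#' @param health_centre_referral_fraction Fraction of health-centre cases
#'   referred onward to hospital (default 0.5).
#' @param transport_km Distance per emergency-transport leg, km (default 10).
#' @param blood_units_per_transfusion Units of blood per transfusion
#'   (default 1).
#' @param severe_pph_extra_cost Extra per-case cost attached to severe PPH
#'   (default 0).
#' @return A `treatment_recipe` object.
#' @export
treatment_recipe <- function(hospital_stay_fraction = 0.5,
                             hospital_stay_nights = 7,
                             health_centre_stay_fraction = 0.5,
                             health_centre_stay_nights = 2,
                             health_post_referral_fraction = 1,
                             referral_split_health_centre = 0.5,
                             health_centre_referral_fraction = 0.5,
                             transport_km = 10,
                             blood_units_per_transfusion = 1,
                             severe_pph_extra_cost = 0) {
  fracs <- c(hospital_stay_fraction, health_centre_stay_fraction,
             health_post_referral_fraction, referral_split_health_centre,
             health_centre_referral_fraction)
  if (any(!vapply(as.list(fracs), is_scalar_number, logical(1))) ||
      any(fracs < 0) || any(fracs > 1)) {
    stopf("invalid recipe: fractions must lie in [0, 1]")
  }
  quants <- c(hospital_stay_nights, health_centre_stay_nights, transport_km,
              blood_units_per_transfusion, severe_pph_extra_cost)
  if (any(!vapply(as.list(quants), is_scalar_number, logical(1))) || any(quants < 0)) {
    stopf("invalid recipe: quantities must be non-negative")
  }
  structure(list(hospital_stay_fraction = hospital_stay_fraction,
                 hospital_stay_nights = hospital_stay_nights,
                 health_centre_stay_fraction = health_centre_stay_fraction,
                 health_centre_stay_nights = health_centre_stay_nights,
                 health_post_referral_fraction = health_post_referral_fraction,
                 referral_split_health_centre = referral_split_health_centre,
                 health_centre_referral_fraction = health_centre_referral_fraction,
                 transport_km = transport_km,
                 blood_units_per_transfusion = blood_units_per_transfusion,
                 severe_pph_extra_cost = severe_pph_extra_cost),
            class = "treatment_recipe")
}

per_dose_cost <- function(prophylaxis, costs, doses, bound) {
  switch(prophylaxis,
    none = 0,
    oxytocin = cost_value(costs, "oxytocin_10iu", bound) +
      if (doses$include_syringe_in_prophylaxis) cost_value(costs, "syringe", bound) else 0,
    misoprostol = doses$misoprostol_tablets_per_dose *
      cost_value(costs, "misoprostol_200ug", bound))
}

#' Prophylactic drug cost for a strategy
#'
#' Births per setting times the per-dose cost of that setting's
#' prophylaxis, summed over settings, unrounded.
#'
#' @param strategy A [strategy()].
#' @param cohort_size,mix Cohort size and [setting_mix()].
#' @param costs A [unit_cost_table()].
#' @param doses A [dose_schedule()].
#' @param bound Cost bound (`"point"`, `"low"`, `"high"`).
#' @return Unrounded cost in model currency.
#' @examples
#' prophylaxis_cost(strategy("oxytocin", "none"), 1000, setting_mix(0.4))  # 87.36
#' @export
prophylaxis_cost <- function(strategy, cohort_size = 1000, mix = setting_mix(),
                             costs = default_costs(), doses = dose_schedule(),
                             bound = "point") {
  stopifnot(inherits(strategy, "strategy"), inherits(mix, "setting_mix"))
  bound <- match_bound(bound)
  cohort_size * mix$hospital * per_dose_cost(strategy$hospital, costs, doses, bound) +
    cohort_size * mix$community * per_dose_cost(strategy$community, costs, doses, bound)
}

#' Per-case treatment cost by setting of origin
#'
#' The treatment bundle (therapeutic oxytocin, syringe, IV fluids,
#' infusion set) is common to all cases. A hospital-origin case adds the
#' expected inpatient-stay cost. A community-origin case adds one
#' emergency-transport leg, then splits between the health-centre path
#' (health-centre stay plus onward referral with a second transport leg
#' and the hospital stay) and the direct hospital path.
#'
#' @param setting `"hospital"` or `"community"` (setting of the birth).
#' @param recipe A [treatment_recipe()].
#' @inheritParams prophylaxis_cost
#' @return Expected cost per PPH case in model currency.
#' @examples
#' per_case_treatment_cost("hospital")  # 14.5434 with default recipe/costs
#' @export
per_case_treatment_cost <- function(setting = c("hospital", "community"),
                                    recipe = treatment_recipe(),
                                    costs = default_costs(), bound = "point") {
  setting <- match.arg(setting)
  stopifnot(inherits(recipe, "treatment_recipe"))
  bound <- match_bound(bound)
  bundle <- cost_value(costs, "oxytocin_10iu", bound) +
    cost_value(costs, "syringe", bound) +
    cost_value(costs, "iv_fluids", bound) +
    cost_value(costs, "infusion_set", bound)
  transport <- recipe$transport_km * cost_value(costs, "transport_per_km", bound)
  hospital_stay <- recipe$hospital_stay_fraction * recipe$hospital_stay_nights *
    cost_value(costs, "overnight_hospital", bound)
  if (setting == "hospital") {
    return(bundle + hospital_stay)
  }
  hc_stay <- recipe$health_centre_stay_fraction * recipe$health_centre_stay_nights *
    cost_value(costs, "overnight_health_centre", bound)
  hc_path <- hc_stay + recipe$health_centre_referral_fraction * (transport + hospital_stay)
  referred <- recipe$health_post_referral_fraction *
    (transport +
       recipe$referral_split_health_centre * hc_path +
       (1 - recipe$referral_split_health_centre) * hospital_stay)
  bundle + referred
}

#' PPH treatment cost for a cohort result
#'
#' Sums, over settings, PPH cases times the per-case cost of their setting
#' of origin, plus additional-uterotonic cases times the uterotonic bundle
#' (oxytocin + syringe), plus transfusions times blood units and giving
#' set, plus any configured severe-PPH extra cost. Linear in every event
#' count: zero events cost zero.
#'
#' @param cohort A `cohort_result` from [evaluate_strategy()].
#' @inheritParams per_case_treatment_cost
#' @return Unrounded cost in model currency.
#' @export
treatment_cost <- function(cohort, recipe = treatment_recipe(),
                           costs = default_costs(), bound = "point") {
  stopifnot(inherits(cohort, "cohort_result"))
  bound <- match_bound(bound)
  row <- function(oc) cohort[cohort$outcome == oc, , drop = FALSE]
  pph <- row("pph")
  uterotonic_bundle <- cost_value(costs, "oxytocin_10iu", bound) +
    cost_value(costs, "syringe", bound)
  transfusion_cost <- recipe$blood_units_per_transfusion *
    (cost_value(costs, "blood_unit", bound) + cost_value(costs, "blood_giving_set", bound))
  pph$hospital * per_case_treatment_cost("hospital", recipe, costs, bound) +
    pph$community * per_case_treatment_cost("community", recipe, costs, bound) +
    row("additional_uterotonics")$total * uterotonic_bundle +
    row("blood_transfusion")$total * transfusion_cost +
    row("severe_pph")$total * recipe$severe_pph_extra_cost
}

#' Assemble a cost breakdown
#'
#' @param prophylaxis_drug_cost,pph_treatment_cost Component costs in
#'   model currency.
#' @return A `cost_breakdown` with `total` equal to their sum.
#' @export
cost_breakdown <- function(prophylaxis_drug_cost, pph_treatment_cost) {
  if (!is_scalar_number(prophylaxis_drug_cost) || !is_scalar_number(pph_treatment_cost) ||
      prophylaxis_drug_cost < 0 || pph_treatment_cost < 0) {
    stopf("invalid parameter: cost components must be non-negative numbers")
  }
  structure(list(prophylaxis_drug_cost = prophylaxis_drug_cost,
                 pph_treatment_cost = pph_treatment_cost,
                 total = prophylaxis_drug_cost + pph_treatment_cost),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("Drugs for prevention: $%.2f\n", x$prophylaxis_drug_cost))
  cat(sprintf("Treatment of PPH:     $%.2f\n", x$pph_treatment_cost))
  cat(sprintf("Total cost:           $%.2f\n", x$total))
  invisible(x)
}

#' Incremental costs between two breakdowns
#'
#' Componentwise differences (intervention minus comparator), unrounded,
#' with whole-dollar reported values (half away from zero). The identity
#' incremental total = incremental drug + incremental treatment holds
#' exactly on the unrounded values.
#'
#' @param intervention,comparator [cost_breakdown()] objects.
#' @return List with `drug`, `treatment`, `total` (unrounded) and
#'   `reported` (whole-dollar integers).
#' @export
total_and_incremental_cost <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "cost_breakdown"), inherits(comparator, "cost_breakdown"))
  drug <- intervention$prophylaxis_drug_cost - comparator$prophylaxis_drug_cost
  treat <- intervention$pph_treatment_cost - comparator$pph_treatment_cost
  total <- intervention$total - comparator$total
  list(drug = drug, treatment = treat, total = total,
       reported = c(drug = round_half_away(drug),
                    treatment = round_half_away(treat),
                    total = round_half_away(total)))
}

#' Apply a scalar inflation factor to an amount
#'
#' Currency adjustment is a plain multiplication by a consumer-price-index
#' ratio supplied by the user; no price series is fetched.
#'
#' @param amount Money amount.
#' @param factor Positive inflation factor.
#' @return `amount * factor`.
#' @export
inflate_cost <- function(amount, factor) {
  if (!is.numeric(amount) || !is_scalar_number(factor) || factor <= 0) {
    stopf("invalid parameter: factor must be a positive number")
  }
  amount * factor
}
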