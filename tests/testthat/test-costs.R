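test_that("prophylaxis cost follows the per-dose arithmetic of the published table", {
  costs <- default_costs()
  doses <- dose_schedule()
  expect_equal(prophylaxis_cost(strategy("oxytocin", "none"), 1000, setting_mix(0.4),
                                costs, doses), 400 * 0.2184)  # 87.36, reported $87
  expect_equal(prophylaxis_cost(strategy("oxytocin", "misoprostol"), 1000, setting_mix(0.4),
                                costs, doses), 400 * 0.2184 + 600 * 3 * 0.09)  # 249.36
  expect_equal(prophylaxis_cost(strategy("misoprostol", "misoprostol"), 1000, setting_mix(0.4),
                                costs, doses), 270)
  expect_equal(prophylaxis_cost(strategy("none", "none"), 1000, setting_mix(0.4),
                                costs, doses), 0)
  # syringe joins the oxytocin dose only when configured
  with_syringe <- dose_schedule(include_syringe_in_prophylaxis = TRUE)
  expect_equal(prophylaxis_cost(strategy("oxytocin", "none"), 1000, setting_mix(0.4),
                                costs, with_syringe), 400 * (0.2184 + 0.07))
})

test_that("per-case treatment costs match hand arithmetic over the unit costs", {
  # bundle = oxytocin 0.2184 + syringe 0.07 + IV fluids 1.79 + infusion set 0.32
  bundle <- 0.2184 + 0.07 + 1.79 + 0.32
  hosp_stay <- 0.5 * 7 * 3.47
  expect_equal(per_case_treatment_cost("hospital"), bundle + hosp_stay)  # 14.5434
  expect_equal(per_case_treatment_cost("hospital"), 14.5434)

  transport <- 10 * 0.41
  hc_path <- 0.5 * 2 * 1.39 + 0.5 * (transport + hosp_stay)
  community <- bundle + transport + 0.5 * hc_path + 0.5 * hosp_stay
  expect_equal(per_case_treatment_cost("community"), community)  # 17.32715
})

test_that("treatment cost is linear in event counts and zero at zero events", {
  expect_equal(treatment_cost(make_cohort_result()), 0)

  # one transfusion only: one blood unit plus one giving set
  one_transfusion <- make_cohort_result(hospital = c(0, 0, 0, 1, 0, 0))
  expect_equal(treatment_cost(one_transfusion), 41.67 + 0.48)  # 42.15

  one_uterotonic <- make_cohort_result(community = c(0, 0, 1, 0, 0, 0))
  expect_equal(treatment_cost(one_uterotonic), 0.2184 + 0.07)

  one_hospital_pph <- make_cohort_result(hospital = c(1, 0, 0, 0, 0, 0))
  expect_equal(treatment_cost(one_hospital_pph), 14.5434)

  # linearity: tripling every count triples the cost
  mixed <- make_cohort_result(hospital = c(3, 1, 2, 1, 0, 0),
                              community = c(5, 2, 4, 1, 0, 0))
  tripled <- make_cohort_result(hospital = 3 * c(3, 1, 2, 1, 0, 0),
                                community = 3 * c(5, 2, 4, 1, 0, 0))
  expect_equal(treatment_cost(tripled), 3 * treatment_cost(mixed), tolerance = 1e-12)

  # shivering and fever management is deliberately uncosted
  side_effects_only <- make_cohort_result(hospital = c(0, 0, 0, 0, 50, 40))
  expect_equal(treatment_cost(side_effects_only), 0)
})

test_that("doubling every unit cost doubles the treatment cost exactly", {
  raw <- yaml::read_yaml(system.file("extdata", "unit_costs.yaml", package = "pphcca"))
  doubled <- unit_cost_table(lapply(raw, function(x) lapply(x, function(v) 2 * v)))
  cohort <- make_cohort_result(hospital = c(10, 2, 5, 1, 30, 8),
                               community = c(20, 3, 9, 2, 60, 15))
  expect_equal(treatment_cost(cohort, costs = doubled),
               2 * treatment_cost(cohort), tolerance = 1e-12)
})

test_that("treatment cost is monotone in transport distance and stay fractions", {
  cohort <- make_cohort_result(hospital = c(10, 0, 0, 0, 0, 0),
                               community = c(20, 0, 0, 0, 0, 0))
  base <- treatment_cost(cohort)
  expect_gt(treatment_cost(cohort, treatment_recipe(transport_km = 25)), base)
  expect_gt(treatment_cost(cohort, treatment_recipe(hospital_stay_fraction = 0.9)), base)
  expect_gt(treatment_cost(cohort, treatment_recipe(health_centre_stay_fraction = 1)), base)
  expect_equal(treatment_cost(cohort, treatment_recipe(transport_km = 0)),
               treatment_cost(cohort) - 20 * (10 * 0.41) * (1 + 0.5 * 0.5))
  expect_error(treatment_recipe(transport_km = -1), "invalid recipe")
  expect_error(treatment_recipe(hospital_stay_fraction = 1.4), "invalid recipe")
})

test_that("cost breakdowns keep the total identity and difference componentwise", {
  a <- cost_breakdown(249.36, 2259.7117)
  b <- cost_breakdown(87.36, 2797.8026)
  expect_equal(a$total, a$prophylaxis_drug_cost + a$pph_treatment_cost, tolerance = 1e-12)
  inc <- total_and_incremental_cost(a, b)
  expect_equal(inc$total, inc$drug + inc$treatment, tolerance = 1e-9)
  expect_equal(inc$drug, 162)
  same <- total_and_incremental_cost(a, a)
  expect_equal(unname(unlist(same[c("drug", "treatment", "total")])), c(0, 0, 0))
})

test_that("drug repricing and stay overrides edit only their own items", {
  low <- reprice_drugs(default_costs(), "low")
  expect_equal(cost_value(low, "oxytocin_10iu"), 0.0368)
  expect_equal(cost_value(low, "misoprostol_200ug"), 0.0564)
  expect_equal(cost_value(low, "iv_fluids"), 1.79)

  stays <- override_stay_costs(default_costs(), 20, 50)
  expect_equal(cost_value(stays, "overnight_health_centre"), 20)
  expect_equal(cost_value(stays, "overnight_hospital"), 50)
  expect_equal(cost_value(stays, "blood_unit"), 41.67)
})

test_that("inflation is a pure multiplication", {
  expect_equal(inflate_cost(100, 1.0), 100)
  expect_equal(inflate_cost(100, 1.4), 140)
  expect_equal(inflate_cost(0.09, 2.0), 0.18)
  expect_error(inflate_cost(100, 0), "invalid parameter")
})
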