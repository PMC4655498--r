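write_yaml_config <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}

test_that("a minimal config naming only the strategies yields the base case", {
  path <- write_yaml_config(c(
    "intervention: {hospital: oxytocin, community: misoprostol}",
    "comparator:   {hospital: oxytocin, community: none}"))
  on.exit(unlink(path))
  config <- load_model_config(path)
  expect_equal(config$pair$cohort_size, 1000)
  expect_equal(config$pair$mix, setting_mix(0.4))
  expect_identical(config$pair$rr_bound, "point")
  comp <- run_model(config)
  expect_identical(comp$increments$reported,
                   c(-22, -2, -6, -4, 130, 42))
})

test_that("config validation names the offending key", {
  bad_mix <- write_yaml_config(c(
    "intervention: {hospital: oxytocin, community: misoprostol}",
    "comparator:   {hospital: oxytocin, community: none}",
    "mix: {hospital: 1.2}"))
  on.exit(unlink(bad_mix), add = TRUE)
  expect_error(load_model_config(bad_mix), "mix")

  bad_drug <- write_yaml_config(c(
    "intervention: {hospital: oxytocin, community: ergometrine}",
    "comparator:   {hospital: oxytocin, community: none}"))
  on.exit(unlink(bad_drug), add = TRUE)
  expect_error(load_model_config(bad_drug), "intervention")

  unknown <- write_yaml_config(c(
    "intervention: {hospital: oxytocin, community: misoprostol}",
    "comparator:   {hospital: oxytocin, community: none}",
    "discounting: 0.03"))
  on.exit(unlink(unknown), add = TRUE)
  expect_error(load_model_config(unknown), "discounting")

  # evidence file with a missing outcome is refused before computation
  ev_path <- tempfile(fileext = ".yaml")
  on.exit(unlink(ev_path), add = TRUE)
  ev <- yaml::read_yaml(system.file("extdata", "evidence_tuncalp.yaml", package = "pphcca"))
  ev$baseline_rates$placebo$fever <- NULL
  yaml::write_yaml(ev, ev_path)
  cfg_path <- write_yaml_config(c(
    "intervention: {hospital: oxytocin, community: misoprostol}",
    "comparator:   {hospital: oxytocin, community: none}",
    sprintf("evidence_file: %s", ev_path)))
  on.exit(unlink(cfg_path), add = TRUE)
  expect_error(load_model_config(cfg_path), "evidence incomplete")
})

test_that("config blocks reach the recipe, doses and bounds", {
  path <- write_yaml_config(c(
    "intervention: {hospital: misoprostol, community: misoprostol}",
    "comparator:   {hospital: none, community: none}",
    "rr_bound: low",
    "cost_bound: point",
    "treatment_cost_multiplier: 2",
    "recipe: {transport_km: 5, blood_units_per_transfusion: 2}",
    "doses: {misoprostol_tablets_per_dose: 2}"))
  on.exit(unlink(path))
  config <- load_model_config(path)
  expect_identical(config$pair$rr_bound, "low")
  expect_equal(config$recipe$transport_km, 5)
  expect_equal(config$recipe$blood_units_per_transfusion, 2)
  expect_equal(config$doses$misoprostol_tablets_per_dose, 2)
  comp <- run_model(config)
  expect_equal(comp$intervention_cost$prophylaxis_drug_cost, 1000 * 2 * 0.09)
})

test_that("the comparison layout carries reported and raw columns that agree", {
  comp <- run_model(base_case_config())
  tab <- render_comparison(comp)
  expect_identical(tab$row[1:2], c("PPH", "Severe PPH"))
  expect_identical(nrow(tab), 9L)
  expect_equal(tab$increment, round_half_away(tab$increment_raw))
  expect_equal(tab$intervention, round_half_away(tab$intervention_raw))
  expect_identical(tab$increment[tab$row == "PPH"], -22)
  expect_identical(tab$increment[tab$row == "Drugs for prevention"], 162)
  # total row is the sum of the component rows, unrounded
  expect_equal(tab$increment_raw[tab$row == "Total cost"],
               sum(tab$increment_raw[tab$row %in% c("Drugs for prevention", "Treatment of PPH")]),
               tolerance = 1e-9)
})

test_that("result CSVs round-trip the unrounded values at full precision", {
  comp <- run_model(base_case_config())
  tab <- render_comparison(comp)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_result_table(tab, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_identical(back$increment_raw, tab$increment_raw)
  expect_identical(back$intervention_raw, tab$intervention_raw)
})

test_that("the command-line front end drives the engines end to end", {
  cfg <- write_yaml_config(c(
    "intervention: {hospital: oxytocin, community: misoprostol}",
    "comparator:   {hospital: oxytocin, community: none}"))
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(cfg, out)), add = TRUE)
  expect_output(pphcca_cli(c("run", "--config", cfg, "--out", out)), "wrote")
  tab <- read.csv(out, stringsAsFactors = FALSE)
  expect_identical(tab$increment[tab$row == "PPH"], -22L)

  trials_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(trials_csv), add = TRUE)
  write.csv(dl_fixture_trials(), trials_csv, row.names = FALSE)
  expect_output(pphcca_cli(c("pool", "--trials", trials_csv)), "Pooled RR")

  plan <- tempfile(fileext = ".yaml")
  on.exit(unlink(plan), add = TRUE)
  writeLines(c("- {target: rr_bound, value: low}",
               "- {target: treatment_cost_multiplier, value: 0.5}"), plan)
  sens_out <- tempfile(fileext = ".csv")
  on.exit(unlink(sens_out), add = TRUE)
  expect_output(pphcca_cli(c("sensitivity", "--config", cfg, "--plan", plan,
                             "--out", sens_out)), "wrote")
  sens <- read.csv(sens_out, stringsAsFactors = FALSE)
  expect_identical(nrow(sens), 3L)
  expect_identical(sens$pph, c(-22L, -38L, -22L))

  expect_error(pphcca_cli(c("run")), "requires --config")
  expect_error(pphcca_cli(c("frobnicate", "--x", "1")), "unknown command")
})
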