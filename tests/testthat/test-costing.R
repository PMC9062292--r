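profile <- patient_profile(65, 1.72, 70)

test_that("dosing rules reproduce the per-kg, per-BSA and Calvert doses", {
  ly <- drug_component("ly01008", 15, 24.99, "per_kg", 15)
  pac <- drug_component("paclitaxel", 175, 57.51, "per_bsa", 175)
  carb <- drug_component("carboplatin", 6, 1.37, "calvert", 6)
  expect_equal(dose_mg(ly, profile), 975)          # 15 mg/kg x 65 kg
  expect_equal(dose_mg(pac, profile), 301)         # 175 mg/m2 x 1.72 m2
  expect_equal(dose_mg(carb, profile), 570)        # 6 x (70 + 25)
  expect_error(drug_component("x", 0, 1, "per_kg", 15), "unit_mg")
  expect_error(drug_component("x", 15, 1, "per_kg", -1), "dose_value")
})

test_that("linear billing prorates per mg and matches the published arithmetic", {
  ly <- drug_component("ly01008", 15, 24.99, "per_kg", 15)
  carb <- drug_component("carboplatin", 6, 1.37, "calvert", 6)
  expect_equal(drug_cost_per_cycle(list(ly), profile, 1), 65 * 24.99)   # 1624.35
  expect_equal(drug_cost_per_cycle(list(carb), profile, 1), 95 * 1.37)  # 130.15
  half <- drug_component("ly01008", 15, 24.99, "per_kg", 7.5)
  expect_equal(drug_cost_per_cycle(list(half), profile, 1), 812.175)
  # component cap: nothing charged beyond cycles_cap
  capped <- drug_component("carboplatin", 6, 1.37, "calvert", 6, cycles_cap = 5)
  expect_equal(drug_cost_per_cycle(list(capped), profile, c(5, 6)),
               c(130.15, 0))
})

test_that("vial billing rounds units up and never undercuts linear billing", {
  set.seed(3)
  for (i in 1:20) {
    comp <- drug_component("x", runif(1, 1, 200), runif(1, 0.5, 100),
                           sample(c("per_kg", "per_bsa", "calvert"), 1),
                           runif(1, 1, 20))
    lin <- drug_cost_per_cycle(list(comp), profile, 1, "linear")
    vial <- drug_cost_per_cycle(list(comp), profile, 1, "vial")
    expect_gte(vial, lin)
    expect_lte(vial - lin, comp$unit_price)
  }
  ly <- drug_component("ly01008", 400, 666.4, "per_kg", 15)  # vial-sized unit
  expect_equal(drug_cost_per_cycle(list(ly), profile, 1, "vial"), 3 * 666.4)
})

test_that("state costs assign management, palliative and AE components as specified", {
  arm <- build_arm(base_cfg, "chemo")
  p1 <- default_config(p_subsequent_therapy = 1)
  p0 <- default_config(p_subsequent_therapy = 0)
  pd_only <- c(pfs_on = 0, pfs_off = 0, pd = 1)
  expect_equal(unname(state_cost(pd_only, 0, arm, p1, cycle = 2)[["total"]]),
               854.05)
  expect_equal(unname(state_cost(pd_only, 0, arm, p0, cycle = 2)[["total"]]),
               337.50)
  dead <- c(pfs_on = 0, pfs_off = 0, pd = 0)
  expect_equal(unname(state_cost(dead, 1, arm, base_cfg, cycle = 2)[["total"]]),
               2627.80)
  # AE lump charged to the whole cohort in cycle 1 only
  start <- c(pfs_on = 1, pfs_off = 0, pd = 0)
  c1 <- state_cost(start, 0, arm, base_cfg, cycle = 1)
  c2 <- state_cost(start, 0, arm, base_cfg, cycle = 2)
  expect_equal(unname(c1[["ae"]]), 745.01)
  expect_equal(unname(c2[["ae"]]), 0)
})

test_that("arm costs are monotone in prices and vanish when everything is free", {
  cost_with <- function(params) {
    cfg <- default_config(params = params)
    run_arm(cfg, "combo")$cost
  }
  base_cost <- cost_with(list())
  for (nm in c("price_ly01008", "price_paclitaxel", "price_carboplatin",
               "cost_followup", "cost_subsequent", "cost_bsc",
               "cost_palliative", "cost_ae_combo")) {
    up <- list(); up[[nm]] <- base_cfg$params[[nm]] * 1.5
    expect_gt(cost_with(up), base_cost)
  }
  zero <- as.list(setNames(rep(0, 10), c(
    "price_ly01008", "price_paclitaxel", "price_carboplatin", "price_nivolumab",
    "cost_followup", "cost_subsequent", "cost_bsc", "cost_palliative",
    "cost_ae_combo", "cost_ae_chemo")))
  expect_equal(cost_with(zero), 0)
})

test_that("halving the dose halves only the LY01008 component, exactly", {
  base <- run_arm(base_cfg, "combo")
  half <- run_arm(base_cfg, "combo", dose_multiplier = 0.5)
  cb <- base$cost_components
  ch <- half$cost_components
  expect_equal(ch[["drug_ly01008"]], cb[["drug_ly01008"]] / 2,
               tolerance = 1e-12)
  for (nm in setdiff(names(cb), "drug_ly01008")) {
    expect_equal(ch[[nm]], cb[[nm]], tolerance = 1e-12)
  }
  expect_equal(base$cost - half$cost, cb[["drug_ly01008"]] / 2,
               tolerance = 1e-9)
  expect_equal(base$qalys, half$qalys, tolerance = 1e-15)
})

test_that("per-cycle cost breakdown reconciles with the accumulated totals", {
  arm <- build_arm(base_cfg, "chemo")
  trace <- run_cohort(arm, base_cfg)
  bk <- cycle_cost_breakdown(trace, arm, base_cfg)
  res <- accumulate(trace, arm, base_cfg)
  n <- n_cycles(base_cfg)
  df_start <- discount_factor(base_cfg, 0:(n - 1))
  df_end <- discount_factor(base_cfg, 1:n)
  disc_total <- sum(df_start * (bk$drug + bk$followup + bk$pd_management)) +
    sum(df_end * (bk$palliative + bk$ae))
  expect_equal(disc_total, res$cost, tolerance = 1e-9)
})
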