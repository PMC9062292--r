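test_that("cohort traces conserve mass, keep death monotone and absorb the cohort", {
  for (arm_name in c("chemo", "combo")) {
    arm <- build_arm(base_cfg, arm_name)
    trace <- run_cohort(arm, base_cfg)
    occ <- as.matrix(trace[, c("pfs_on", "pfs_off", "pd", "death")])
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-12)
    expect_true(all(occ > -1e-15))
    expect_true(all(diff(trace$death) >= 0))
    expect_identical(unname(occ[1, ]), c(1, 0, 0, 0))
    expect_equal(trace$death, cumsum(trace$new_deaths), tolerance = 1e-12)
    # 30-year horizon: near-complete absorption in both arms
    expect_gt(trace$death[nrow(trace)], 0.99)
  }
})

test_that("convolution engine equals the explicit per-cohort loop oracle", {
  cfg <- short_cfg
  for (arm_name in c("chemo", "combo")) {
    arm <- build_arm(cfg, arm_name)
    engine <- run_cohort(arm, cfg)
    oracle <- loop_cohort(arm, cfg)
    for (col in c("pfs_on", "pfs_off", "pd", "death", "new_deaths")) {
      expect_lt(max(abs(engine[[col]] - oracle[[col]])), 1e-12)
    }
  }
})

test_that("engine equals an age-expanded transition-matrix product over short horizons", {
  # states: pfs_on, pfs_off, pd age 1..n, death; built independently of the
  # engine from the per-cycle probabilities
  n <- 5
  cfg <- default_config(horizon_years = n * 21 / 365.25 + 1e-9)
  expect_identical(n_cycles(cfg), 5L)
  for (arm_name in c("chemo", "combo")) {
    arm <- build_arm(cfg, arm_name)
    state <- c(1, 0, rep(0, n), 0)
    rows <- matrix(NA_real_, n + 1, n + 3)
    rows[1, ] <- state
    for (t in seq_len(n)) {
      q_prog <- wb_cond_exit_prob(arm$pfs, t)
      q_os <- wb_cond_exit_prob(arm$os, t)
      on_tx <- t <= arm$tx_cycles
      q_exit_on <- if (on_tx) 1 - (1 - q_prog) * (1 - q_os) else q_prog
      p_disc <- if (on_tx) arm$p_discontinue_ae else 0
      m <- matrix(0, n + 3, n + 3)
      m[1, 1] <- (1 - q_exit_on) * (1 - p_disc)       # stay on treatment
      m[1, 2] <- (1 - q_exit_on) * p_disc             # discontinue
      m[2, 2] <- 1 - q_prog                           # stay off treatment
      # progression: enter PD age 1, facing that cycle's first death risk
      q1 <- wb_cond_exit_prob(arm$os, 1)
      m[1, 3] <- q_exit_on * (1 - q1); m[1, n + 3] <- q_exit_on * q1
      m[2, 3] <- q_prog * (1 - q1);    m[2, n + 3] <- m[2, n + 3] + q_prog * q1
      for (a in seq_len(n - 1)) {                     # PD ageing
        qa <- wb_cond_exit_prob(arm$os, a + 1)
        m[2 + a, 3 + a] <- 1 - qa
        m[2 + a, n + 3] <- qa
      }
      m[n + 2, n + 3] <- 1                            # oldest PD bucket
      m[n + 3, n + 3] <- 1                            # death absorbing
      state <- drop(state %*% m)
      rows[t + 1, ] <- state
    }
    engine <- run_cohort(arm, cfg)
    expect_lt(max(abs(engine$pfs_on - rows[, 1])), 1e-12)
    expect_lt(max(abs(engine$pfs_off - rows[, 2])), 1e-12)
    expect_lt(max(abs(engine$pd - rowSums(rows[, 3:(n + 2)]))), 1e-12)
    expect_lt(max(abs(engine$death - rows[, n + 3])), 1e-12)
  }
})

test_that("transition probabilities match the printed per-cycle formulas", {
  chemo <- build_arm(base_cfg, "chemo")
  tp <- transition_probabilities(chemo, base_cfg, 1)
  expect_equal(tp$pfs_off_exit, 1 - exp(-0.003867), tolerance = 1e-12)
  expect_equal(tp$pd_death, 1 - exp(-0.004716), tolerance = 1e-12)
  expect_equal(tp$pfs_on_exit,
               1 - exp(-0.003867) * exp(-0.004716), tolerance = 1e-12)
  expect_equal(tp$p_discontinue, 0.006372)
  # past the chemotherapy cap: progression only, no AE discontinuation
  tp9 <- transition_probabilities(chemo, base_cfg, 9)
  expect_equal(tp9$pfs_on_exit, tp9$pfs_off_exit)
  expect_identical(tp9$p_discontinue, 0)
  # exhaustive sweep: outflows stay within [0, 1] for every cycle, both arms
  for (arm in list(chemo, build_arm(base_cfg, "combo"))) {
    for (t in c(1:20, seq(30, 521, by = 30))) {
      tp <- transition_probabilities(arm, base_cfg, t, pd_age = min(t, 50))
      expect_true(all(unlist(tp) >= 0 & unlist(tp) <= 1))
    }
  }
})

test_that("no discontinuation means an empty off-treatment substate", {
  cfg <- default_config(params = list(p_disc_chemo = 0, p_disc_combo = 0))
  for (arm_name in c("chemo", "combo")) {
    trace <- run_cohort(build_arm(cfg, arm_name), cfg)
    expect_identical(max(trace$pfs_off), 0)
  }
})

test_that("arms with identical hazards, discontinuation and regimen duration coincide", {
  cfg <- default_config(params = list(
    hr_os = 1, hr_pfs = 1, p_disc_combo = 0.006372, p_disc_chemo = 0.006372))
  chemo <- build_arm(cfg, "chemo")
  combo <- build_arm(cfg, "combo")
  combo$tx_cycles <- chemo$tx_cycles  # align the treatment window too
  expect_equal(run_cohort(combo, cfg), run_cohort(chemo, cfg),
               tolerance = 1e-15)
})

test_that("stronger OS hazard ratios never reduce life-years or QALYs", {
  prev_ly <- -Inf; prev_q <- -Inf
  for (hr in c(1, 0.8, 0.654, 0.4)) {
    cfg <- default_config(params = list(hr_os = hr))
    res <- run_arm(cfg, "combo")
    expect_gte(res$life_years, prev_ly)
    expect_gte(res$qalys, prev_q)
    prev_ly <- res$life_years; prev_q <- res$qalys
  }
})

test_that("combination arm outlives chemotherapy under favourable hazard ratios", {
  chemo <- run_arm(base_cfg, "chemo")
  combo <- run_arm(base_cfg, "combo")
  expect_gt(combo$life_years, chemo$life_years)
  expect_gt(combo$qalys, chemo$qalys)
  # utilities <= 1 and positive discounting: QALYs below undiscounted life-years
  expect_lte(chemo$qalys, chemo$life_years)
})

test_that("with no discounting and perfect utilities QALYs equal life-years", {
  cfg <- default_config(params = list(
    discount_rate = 0, u_pfs = 1, u_pd = 1, du_combo = 0, du_chemo = 0))
  for (arm_name in c("chemo", "combo")) {
    res <- run_arm(cfg, arm_name)
    expect_equal(res$qalys, res$life_years, tolerance = 1e-12)
  }
})
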