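test_that("survival function satisfies S(0) = 1, monotonicity and bounds", {
  for (wp in list(os_base, pfs_base, weibull_params(0.1, 1))) {
    expect_identical(wb_survival(wp, 0), 1)
    s <- wb_survival(wp, 0:100)
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s <= 1))
  }
  expect_error(wb_survival(os_base, -1), "non-negative")
  expect_error(weibull_params(-0.1, 1.5), "positive")
  expect_error(weibull_params(0.1, 0), "positive")
})

test_that("analytic medians match root-finding and the cycle-unit anchors", {
  for (wp in list(os_base, pfs_base)) {
    root <- uniroot(function(t) wb_survival(wp, t) - 0.5,
                    c(1e-6, 1e3), tol = 1e-12)$root
    expect_equal(wb_median(wp), root, tolerance = 1e-6)
    expect_equal(wb_survival(wp, wb_median(wp)), 0.5, tolerance = 1e-9)
  }
  # 3-week-cycle time unit: medians ~25.9 cycles (17.9 months) OS,
  # ~9.2 cycles (6.4 months) PFS
  expect_equal(wb_median(os_base), 25.94, tolerance = 0.01)
  expect_equal(wb_median(pfs_base), 9.22, tolerance = 0.01)
})

test_that("conditional exit probability matches 1 - S(t)/S(t-1) and its limits", {
  for (wp in list(os_base, pfs_base)) {
    t <- 1:521
    direct <- wb_cond_exit_prob(wp, t)
    expect_true(all(direct >= 0 & direct <= 1))
    expect_true(all(diff(direct) >= 0))  # increasing hazard for shape > 1
    # ratio oracle where the survival function is still representable
    t_ok <- t[wb_survival(wp, t - 1) > 1e-280]
    ratio <- 1 - wb_survival(wp, t_ok) / wb_survival(wp, t_ok - 1)
    expect_lt(max(abs(wb_cond_exit_prob(wp, t_ok) - ratio)), 1e-12)
    expect_true(all(wb_cond_exit_prob(wp, 1:100) < 1))
  }
  expect_equal(wb_cond_exit_prob(os_base, 1), 1 - exp(-0.004716),
               tolerance = 1e-12)
  tiny <- weibull_params(1e-12, 1.5)
  expect_lt(max(wb_cond_exit_prob(tiny, t)), 1e-9)
  expect_error(wb_cond_exit_prob(os_base, 0), ">= 1")
})

test_that("hazard ratios scale lambda only, compose multiplicatively and order curves", {
  expect_equal(apply_hazard_ratio(os_base, 1), os_base)
  adj <- apply_hazard_ratio(os_base, 0.654)
  expect_equal(adj$scale, 0.004716 * 0.654, tolerance = 1e-12)
  expect_identical(adj$shape, os_base$shape)
  two_step <- apply_hazard_ratio(apply_hazard_ratio(os_base, 0.7), 0.5)
  expect_equal(two_step, apply_hazard_ratio(os_base, 0.35))
  t <- seq(0.5, 200, by = 0.5)
  expect_true(all(wb_survival(apply_hazard_ratio(os_base, 0.5), t) >
                    wb_survival(os_base, t)))
  expect_error(apply_hazard_ratio(os_base, 0), "positive")
  expect_error(apply_hazard_ratio(os_base, -1), "positive")
  expect_error(hazard_ratio_pair(0.654, -0.4), "positive")
  expect_error(hazard_ratio_pair(0.654, 0.405, ci_os = c(0.7, 1.4)), "bracket")
})

test_that("maximum-likelihood fit recovers generating parameters from censored data", {
  spec <- cohort_spec(10000, censor_time = 37, seed = 42)  # ~30% censored
  ipd <- simulate_ipd(spec, "reference")
  expect_gt(mean(ipd$os_event == 0), 0.2)
  expect_lt(mean(ipd$os_event == 0), 0.4)
  fit <- fit_weibull_mle(ipd$os_time, ipd$os_event)
  expect_lt(abs(fit$params$scale - 0.004716) / 0.004716, 0.05)
  expect_lt(abs(fit$params$shape - 1.533854) / 1.533854, 0.05)
  expect_true(fit$se_scale > 0 && fit$se_shape > 0)
})

test_that("fit agrees with an established parametric survival fitter", {
  spec <- cohort_spec(4000, censor_time = 60, seed = 7)
  ipd <- simulate_ipd(spec, "reference")
  fit <- fit_weibull_mle(ipd$os_time, ipd$os_event)
  ref <- flexsurv::flexsurvreg(
    survival::Surv(os_time, os_event) ~ 1, data = ipd, dist = "weibull")
  shape_ref <- unname(ref$res["shape", "est"])
  scale_ref <- unname(ref$res["scale", "est"])^(-shape_ref)  # S(t)=exp(-(t/b)^a)
  expect_equal(fit$params$shape, shape_ref, tolerance = 1e-4)
  expect_equal(fit$params$scale, scale_ref, tolerance = 1e-3)
  expect_equal(fit$loglik, unname(ref$loglik), tolerance = 1e-6)
})

test_that("exponential data are recovered as the shape = 1 special case", {
  spec <- cohort_spec(5000, os_params = weibull_params(0.03, 1),
                      censor_time = 80, seed = 11)
  ipd <- simulate_ipd(spec, "reference")
  fit <- fit_weibull_mle(ipd$os_time, ipd$os_event)
  expect_lt(abs(fit$params$shape - 1), 1.96 * fit$se_shape)
})

test_that("fit errors on degenerate inputs and improves with sample size", {
  expect_error(fit_weibull_mle(c(3, 5, 7), c(1, 0, 0)), "two observed events")
  expect_error(fit_weibull_mle(c(3, 5, 7), c(0, 0, 0)), "two observed events")
  expect_error(fit_weibull_mle(c(-1, 3, 5), c(1, 1, 1)), "positive")
  err_at <- function(n) {
    r <- km_fit_roundtrip(cohort_spec(n, censor_time = 37, seed = 5))
    max(r$rel_error_scale, r$rel_error_shape)
  }
  expect_lt(err_at(10000), err_at(400))
})
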