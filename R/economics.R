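#' Discount factor at a given cycle
#'
#' Continuous-time compounding of the annual rate over the elapsed model time:
#' `(1 + rate)^(-cycle * cycle_days / 365.25)`; equals 1 at cycle 0, and
#' exactly `1/(1+rate)` after one year of cycles.
#'
#' @param config A [default_config()] object.
#' @param cycle Cycle index (>= 0); may be a vector and need not be integer.
#' @export
discount_factor <- function(config, cycle) {
  stopifnot(all(cycle >= 0))
  (1 + config$params$discount_rate)^(-cycle * config$cycle_days / 365.25)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Recurring per-cycle costs and utilities are weighted by the state occupancy
#' at the start of each cycle and discounted at the cycle start; event costs
#' (the first-cycle AE lump and terminal palliative care) are discounted at
#' the end of the cycle in which they occur. QALYs weight person-time by the
#' progression-free utility (less the AE disutility while on first-line
#' treatment) and the progressive-disease utility.
#'
#' @param trace A [run_cohort()] trace.
#' @param arm The [build_arm()] object it was run with.
#' @param config The configuration.
#' @return An object of class `arm_result`: list with `name`, `cost` (US$,
#'   discounted), `qalys` (discounted), `life_years` (undiscounted) and
#'   `cost_components` (named vector of discounted US$ including per-drug
#'   acquisition costs).
#' @export
accumulate <- function(trace, arm, config) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "treatment_arm"))
  p <- config$params
  if (p$u_pfs > 1 || p$u_pfs < 0 || p$u_pd > 1 || p$u_pd < 0 ||
      arm$ae_disutility < 0 ||
      (arm$ae_disutility > 0 && arm$ae_disutility >= p$u_pfs)) {
    stop("utility inputs must lie in [0, 1] with disutility below u_pfs",
         call. = FALSE)
  }
  n <- n_cycles(config)
  cyc_yr <- config$cycle_days / 365.25
  hcc <- config$half_cycle_correction
  df_start <- discount_factor(config, 0:(n - 1))
  df_end <- discount_factor(config, 1:n)
  on <- accrual_weights(trace$pfs_on, n, hcc)
  off <- accrual_weights(trace$pfs_off, n, hcc)
  pd <- accrual_weights(trace$pd, n, hcc)
  deaths <- trace$new_deaths[2:(n + 1)]
  t <- seq_len(n)
  profile <- profile_from_config(config)

  # drug acquisition, per component (needed for the dosage-scenario identity)
  drug_by_comp <- vapply(arm$regimen, function(comp) {
    percyc <- drug_cost_per_cycle(list(comp), profile, t, config$billing)
    sum(df_start * on * percyc)
  }, numeric(1))
  names(drug_by_comp) <- paste0("drug_", vapply(arm$regimen, `[[`, "", "name"))

  followup <- sum(df_start * (on + off) * p$cost_followup)
  pd_mgmt <- sum(df_start * pd *
                   (config$p_subsequent_therapy * p$cost_subsequent +
                      (1 - config$p_subsequent_therapy) * p$cost_bsc))
  palliative <- sum(df_end * deaths * p$cost_palliative)
  ae <- arm$ae_cost * df_end[1]
  components <- c(drug_by_comp, followup = followup, pd_management = pd_mgmt,
                  palliative = palliative, ae = ae)

  on_tx <- t <= arm$tx_cycles
  u_on <- p$u_pfs - ifelse(on_tx, arm$ae_disutility, 0)
  qalys <- sum(df_start * cyc_yr *
                 (on * u_on + off * p$u_pfs + pd * p$u_pd))

  structure(list(name = arm$name, cost = sum(components), qalys = qalys,
                 life_years = life_years(trace, config),
                 cost_components = components),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s\n  discounted cost  US$ %s\n  discounted QALYs %.4f\n  life-years       %.4f\n",
              x$name, format(round(x$cost), big.mark = ","), x$qalys,
              x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness of one strategy against a reference
#'
#' @param reference,comparator [accumulate()] results (`arm_result`), or any
#'   lists with `cost` and `qalys` elements.
#' @return An object of class `ce_result`: `delta_cost`, `delta_qalys`,
#'   `icer` (US$/QALY; `NA` and flagged when the QALY difference is zero), and
#'   a `dominance` label (`"dominant"` when cheaper and more effective,
#'   `"dominated"` when costlier and less effective, otherwise `"none"`).
#' @export
icer <- function(reference, comparator) {
  dc <- comparator$cost - reference$cost
  dq <- comparator$qalys - reference$qalys
  dominance <- if (dc < 0 && dq > 0) "dominant"
               else if (dc > 0 && dq < 0) "dominated"
               else "none"
  structure(list(delta_cost = dc, delta_qalys = dq,
                 icer = if (dq == 0) NA_real_ else dc / dq,
                 icer_defined = dq != 0, dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("incremental cost US$ %s, incremental QALYs %.4f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qalys))
  if (x$icer_defined) {
    cat(sprintf("ICER US$ %s/QALY%s\n", format(round(x$icer), big.mark = ","),
                if (x$dominance != "none") paste0(" (", x$dominance, ")") else ""))
  } else {
    cat("ICER undefined (zero QALY difference)\n")
  }
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `wtp * delta_qalys - delta_cost`; non-negative exactly when the comparator
#' is cost-effective at that threshold (equivalently ICER <= wtp when the
#' QALY gain is positive).
#'
#' @param ce An [icer()] result.
#' @param wtp Willingness to pay per QALY (>= 0).
#' @export
nmb <- function(ce, wtp) {
  stopifnot(inherits(ce, "ce_result"), wtp >= 0)
  wtp * ce$delta_qalys - ce$delta_cost
}

#' Convert between US$ and CNY
#'
#' @param amount Amount(s) of money.
#' @param direction `"usd_to_cny"` or `"cny_to_usd"`.
#' @param fx CNY per US$ (> 0).
#' @export
convert_currency <- function(amount, direction = c("usd_to_cny", "cny_to_usd"),
                             fx = 6.8974) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(fx), fx > 0)
  if (direction == "usd_to_cny") amount * fx else amount / fx
}
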