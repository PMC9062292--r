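#' Run one treatment arm end to end
#'
#' @param config A [default_config()] object.
#' @param arm `"chemo"` or `"combo"`.
#' @param dose_multiplier Multiplier on the LY01008 dose (combination arm).
#' @return An [accumulate()] result with the trace attached as attribute
#'   `"trace"`.
#' @export
run_arm <- function(config, arm = c("chemo", "combo"), dose_multiplier = 1) {
  arm_obj <- build_arm(config, match.arg(arm), dose_multiplier)
  trace <- run_cohort(arm_obj, config)
  res <- accumulate(trace, arm_obj, config)
  attr(res, "trace") <- trace
  res
}

#' Base-case cost-effectiveness analysis
#'
#' Runs both arms (LY01008 at the clinical-trial dosage of 15 mg/kg) through
#' the cohort model and summarises discounted costs, QALYs, the ICER and the
#' net monetary benefit at the configured willingness-to-pay threshold, in
#' both US$ and CNY.
#'
#' @param config A [default_config()] object.
#' @param dose_multiplier Multiplier on the LY01008 dose (1 for the base
#'   case; see [run_scenario()]).
#' @return An object of class `ce_summary`.
#' @export
run_base_case <- function(config = default_config(), dose_multiplier = 1) {
  chemo <- run_arm(config, "chemo")
  combo <- run_arm(config, "combo", dose_multiplier)
  inc <- icer(chemo, combo)
  structure(list(
    reference = chemo, comparator = combo, incremental = inc,
    nmb = nmb(inc, config$wtp_per_qaly),
    wtp = config$wtp_per_qaly, fx = config$fx_cny_per_usd,
    dose_multiplier = dose_multiplier,
    calibration = config$calibration, config = config),
    class = "ce_summary")
}

#' Real-world dosage scenario analysis
#'
#' Identical pipeline with the LY01008 dose multiplied by `dose_multiplier`
#' (default 0.5, i.e. 7.5 mg/kg every 3-week cycle); only drug acquisition
#' costs change, so arm QALYs equal the base case exactly.
#'
#' @param config A [default_config()] object.
#' @param dose_multiplier Multiplier on the 15 mg/kg trial dose.
#' @export
run_scenario <- function(config = default_config(), dose_multiplier = 0.5) {
  run_base_case(config, dose_multiplier = dose_multiplier)
}

#' @export
print.ce_summary <- function(x, ...) {
  fmt <- function(v) format(round(v), big.mark = ",")
  cat(sprintf("Cost-effectiveness summary%s\n",
              if (x$dose_multiplier != 1)
                sprintf(" (LY01008 dose multiplier %.2g)", x$dose_multiplier)
              else ""))
  for (r in list(x$reference, x$comparator)) {
    cat(sprintf("  %-48s US$ %8s  %.2f QALYs\n", r$name, fmt(r$cost), r$qalys))
  }
  inc <- x$incremental
  cat(sprintf("  incremental: US$ %s (CNY %s), %.2f QALYs\n",
              fmt(inc$delta_cost),
              fmt(convert_currency(inc$delta_cost, "usd_to_cny", x$fx)),
              inc$delta_qalys))
  if (inc$icer_defined) {
    cat(sprintf("  ICER: US$ %s/QALY (CNY %s/QALY)\n", fmt(inc$icer),
                fmt(convert_currency(inc$icer, "usd_to_cny", x$fx))))
  } else {
    cat("  ICER undefined (zero QALY difference)\n")
  }
  cat(sprintf("  NMB at WTP US$ %s/QALY: US$ %s -> %scost-effective\n",
              fmt(x$wtp), fmt(x$nmb), if (x$nmb >= 0) "" else "NOT "))
  invisible(x)
}

#' Tidy one-row data frame of a cost-effectiveness summary
#'
#' @param summary A [run_base_case()] result.
#' @export
ce_summary_row <- function(summary) {
  stopifnot(inherits(summary, "ce_summary"))
  inc <- summary$incremental
  data.frame(
    dose_multiplier = summary$dose_multiplier,
    cost_ref_usd = summary$reference$cost, qalys_ref = summary$reference$qalys,
    cost_comp_usd = summary$comparator$cost, qalys_comp = summary$comparator$qalys,
    delta_cost_usd = inc$delta_cost, delta_qalys = inc$delta_qalys,
    icer_usd = inc$icer,
    icer_cny = convert_currency(inc$icer, "usd_to_cny", summary$fx),
    nmb_usd = summary$nmb)
}

#' Write a cost-effectiveness summary as JSON
#'
#' Emits arm-level results (in both currencies), incremental results and the
#' calibration metadata of the structural parameters.
#'
#' @param summary A [run_base_case()] result.
#' @param path Output file path.
#' @export
write_ce_summary <- function(summary, path) {
  stopifnot(inherits(summary, "ce_summary"))
  inc <- summary$incremental
  arm_block <- function(r) list(
    cost_usd = r$cost,
    cost_cny = convert_currency(r$cost, "usd_to_cny", summary$fx),
    qalys = r$qalys, life_years = r$life_years)
  out <- list(
    arms = list(reference = arm_block(summary$reference),
                comparator = arm_block(summary$comparator)),
    incremental = list(
      delta_cost_usd = inc$delta_cost,
      delta_cost_cny = convert_currency(inc$delta_cost, "usd_to_cny", summary$fx),
      delta_qalys = inc$delta_qalys,
      icer_usd = inc$icer,
      icer_cny = convert_currency(inc$icer, "usd_to_cny", summary$fx),
      nmb_usd = summary$nmb, dominance = inc$dominance),
    wtp_usd_per_qaly = summary$wtp,
    dose_multiplier = summary$dose_multiplier,
    calibration_metadata = summary$calibration)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
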