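#' Administered dose of a drug component in mg
#'
#' Applies the component's dosing rule to the patient profile: `per_kg` gives
#' dose-per-kg x weight, `per_bsa` gives dose-per-m^2 x BSA, and `calvert`
#' gives the Calvert formula AUC x (CrCl + 25).
#'
#' @param component A [drug_component()] object.
#' @param profile A [patient_profile()] object.
#' @return Dose in mg.
#' @examples
#' p <- patient_profile(65, 1.72, 70)
#' dose_mg(drug_component("carboplatin", 6, 1.37, "calvert", 6), p)  # 570 mg
#' @export
dose_mg <- function(component, profile) {
  stopifnot(inherits(component, "drug_component"),
            inherits(profile, "patient_profile"))
  switch(component$dose_rule,
         per_kg = component$dose_value * profile$weight,
         per_bsa = component$dose_value * profile$bsa,
         calvert = component$dose_value * (profile$crcl + 25))
}

#' Drug acquisition cost of a regimen in a given cycle
#'
#' Sums component costs for every component still administered at `cycle`
#' (i.e. `cycle <= cycles_cap`). Under `"linear"` billing the dose is priced
#' pro rata per mg (`dose/unit_mg x unit_price`), reflecting the published
#' per-small-unit price normalisation; under `"vial"` billing whole units are
#' charged (`ceiling(dose/unit_mg) x unit_price`).
#'
#' @param regimen List of [drug_component()] objects.
#' @param profile A [patient_profile()] object.
#' @param cycle Treatment cycle index (>= 1); may be a vector.
#' @param billing `"linear"` or `"vial"`.
#' @return Cost in US$ (vectorised over `cycle`).
#' @export
drug_cost_per_cycle <- function(regimen, profile, cycle,
                                billing = c("linear", "vial")) {
  billing <- match.arg(billing)
  stopifnot(all(cycle >= 1))
  cost <- numeric(length(cycle))
  for (comp in regimen) {
    units <- dose_mg(comp, profile) / comp$unit_mg
    if (billing == "vial") units <- ceiling(units)
    cost <- cost + ifelse(cycle <= comp$cycles_cap, units * comp$unit_price, 0)
  }
  cost
}

#' Undiscounted cost breakdown of one trace cycle
#'
#' Costs accrued by the cohort during one cycle: first-line drug plus routine
#' follow-up for patients on treatment, follow-up alone for patients who
#' discontinued, disease management in progressive disease (active subsequent
#' therapy for a proportion `p_subsequent_therapy` of patients, best
#' supportive care for the rest), and one terminal cycle of palliative care
#' per death. The aggregate AE treatment cost is charged once, in the first
#' cycle, to the whole cohort.
#'
#' @param occupancy Named numeric vector with `pfs_on`, `pfs_off`, `pd`.
#' @param new_deaths Proportion of the cohort dying during the cycle.
#' @param arm A [build_arm()] object.
#' @param config A [default_config()] object.
#' @param cycle Cycle index (>= 1, where 1 is the first cycle lived).
#' @param profile A [patient_profile()] object.
#' @return Named vector of undiscounted US$ components: `drug`, `followup`,
#'   `pd_management`, `palliative`, `ae`, `total`.
#' @export
state_cost <- function(occupancy, new_deaths, arm, config, cycle,
                       profile = profile_from_config(config)) {
  p <- config$params
  drug <- occupancy[["pfs_on"]] *
    drug_cost_per_cycle(arm$regimen, profile, cycle, config$billing)
  followup <- (occupancy[["pfs_on"]] + occupancy[["pfs_off"]]) * p$cost_followup
  pd_management <- occupancy[["pd"]] *
    (config$p_subsequent_therapy * p$cost_subsequent +
       (1 - config$p_subsequent_therapy) * p$cost_bsc)
  palliative <- new_deaths * p$cost_palliative
  ae <- if (cycle == 1) arm$ae_cost else 0
  c(drug = drug, followup = followup, pd_management = pd_management,
    palliative = palliative, ae = ae,
    total = drug + followup + pd_management + palliative + ae)
}

#' Patient profile taken from configuration parameters
#'
#' @param config A [default_config()] object.
#' @export
profile_from_config <- function(config) {
  patient_profile(config$params$weight, config$params$bsa, config$params$crcl)
}

#' Per-cycle cost breakdown of a whole trace
#'
#' @param trace A [run_cohort()] trace.
#' @param arm The [build_arm()] object it was run with.
#' @param config The configuration.
#' @return Data frame (one row per accrual cycle) with undiscounted columns
#'   `cycle`, `drug`, `followup`, `pd_management`, `palliative`, `ae`,
#'   `total`, all in US$.
#' @export
cycle_cost_breakdown <- function(trace, arm, config) {
  n <- n_cycles(config)
  profile <- profile_from_config(config)
  hcc <- config$half_cycle_correction
  rows <- lapply(seq_len(n), function(i) {
    occ <- c(pfs_on = accrual_weights(trace$pfs_on, n, hcc)[i],
             pfs_off = accrual_weights(trace$pfs_off, n, hcc)[i],
             pd = accrual_weights(trace$pd, n, hcc)[i])
    state_cost(occ, trace$new_deaths[i + 1], arm, config, i, profile)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(cycle = seq_len(n), out, currency = "USD")
}
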