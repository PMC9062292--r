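# Cohort engine over {PFS on treatment, PFS off treatment, PD, Death}.
#
# Structure (see the methods vignette for the rationale and the candidate
# readings that were rejected):
#   * While receiving first-line drug (PFS-on, cycle <= tx_cycles) the
#     progression hazard and the OS-derived hazard compete as exits from PFS;
#     off treatment (PFS-on beyond the chemo cap, or PFS-off) only the
#     progression hazard applies.
#   * Every PFS exit enters progressive disease; post-progression survival
#     follows the arm's OS Weibull with the clock restarted at progression.
#     Death occurs from the PD state only. Patients progressing during cycle t
#     face their first post-progression death risk within that same cycle.
#   * AE-related discontinuation (PFS-on -> PFS-off) applies to patients who
#     remain progression-free that cycle, while on treatment only.

# cache of the lower-triangular lag index matrix, keyed by n_cycles
.bevcea_cache <- new.env(parent = emptyenv())

lag_index <- function(n) {
  key <- as.character(n)
  if (is.null(.bevcea_cache[[key]])) {
    k <- outer(seq_len(n), seq_len(n), "-") + 1L   # k[t, s] = t - s + 1
    k[k < 1L] <- NA_integer_
    .bevcea_cache[[key]] <- k
  }
  .bevcea_cache[[key]]
}

# convolution of entrant vector e with per-age vector v: out[t] = sum_s e[s] v[t-s+1]
conv_lag <- function(e, v) {
  n <- length(e)
  k <- lag_index(n)
  m <- matrix(0, n, n)
  ok <- !is.na(k)
  m[ok] <- v[k[ok]]
  drop(m %*% e)
}

#' Per-cycle transition probabilities of a treatment arm
#'
#' Outflow probabilities at cycle `t` of the arm's hazard-ratio-adjusted
#' Weibull curves: the PFS exit probability from the on-treatment and
#' off-treatment substates, the effective AE-discontinuation probability among
#' progression-free stayers, and the post-progression death probability at a
#' given time since progression.
#'
#' @param arm A [build_arm()] object.
#' @param config A [default_config()] object.
#' @param t Cycle index (>= 1).
#' @param pd_age Cycles since progression (>= 1) for the PD death probability.
#' @return Named list with `pfs_on_exit`, `pfs_off_exit`, `p_discontinue`,
#'   `pd_death`; all probabilities in \[0, 1\].
#' @export
transition_probabilities <- function(arm, config, t, pd_age = 1) {
  stopifnot(inherits(arm, "treatment_arm"), t >= 1, pd_age >= 1)
  q_prog <- wb_cond_exit_prob(arm$pfs, t)
  q_death <- wb_cond_exit_prob(arm$os, t)
  on_tx <- t <= arm$tx_cycles
  out <- list(
    pfs_on_exit = if (on_tx) 1 - (1 - q_prog) * (1 - q_death) else q_prog,
    pfs_off_exit = q_prog,
    p_discontinue = if (on_tx) arm$p_discontinue_ae else 0,
    pd_death = wb_cond_exit_prob(arm$os, pd_age))
  bad <- vapply(out, function(x) x < 0 || x > 1 || !is.finite(x), logical(1))
  if (any(bad)) {
    stop("transition probabilities fell outside [0, 1]: ",
         paste(names(out)[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Run the cohort model for one treatment arm
#'
#' Iterates the state-occupancy distribution from everyone starting in the
#' PFS-on-treatment state over `n_cycles(config)` cycles, tracking the two PFS
#' substates, progressive disease (as a convolution of progression entrants
#' with the restarted OS survival curve) and death.
#'
#' @param arm A [build_arm()] object.
#' @param config A [default_config()] object.
#' @return An object of class `cohort_trace`: a data frame with columns
#'   `cycle` (0..n), `pfs_on`, `pfs_off`, `pd`, `death` and `new_deaths`
#'   (the proportion dying during that cycle; 0 at cycle 0).
#' @export
run_cohort <- function(arm, config) {
  stopifnot(inherits(arm, "treatment_arm"), inherits(config, "bevcea_config"))
  n <- n_cycles(config)
  t <- seq_len(n)
  q_prog <- wb_cond_exit_prob(arm$pfs, t)
  q_death <- wb_cond_exit_prob(arm$os, t)
  on_tx <- t <= arm$tx_cycles
  q_exit_on <- ifelse(on_tx, 1 - (1 - q_prog) * (1 - q_death), q_prog)
  q_exit_off <- q_prog
  p_disc <- ifelse(on_tx, arm$p_discontinue_ae, 0)

  pfs_on <- numeric(n + 1)
  pfs_off <- numeric(n + 1)
  pfs_on[1] <- 1
  entrants <- numeric(n)
  for (i in t) {
    on <- pfs_on[i]; off <- pfs_off[i]
    entrants[i] <- on * q_exit_on[i] + off * q_exit_off[i]
    stay_on <- on * (1 - q_exit_on[i])
    pfs_on[i + 1] <- stay_on * (1 - p_disc[i])
    pfs_off[i + 1] <- off * (1 - q_exit_off[i]) + stay_on * p_disc[i]
  }

  # post-progression survival: arm OS curve restarted at progression
  q_age <- wb_cond_exit_prob(arm$os, seq_len(n + 1))
  surv_age <- cumprod(1 - q_age)              # S*(a), a = 1..n+1
  death_age <- c(1 - surv_age[1], -diff(surv_age))  # P(die in PD cycle a)
  pd <- numeric(n + 1)
  pd[t + 1] <- conv_lag(entrants, surv_age)
  new_deaths <- c(0, conv_lag(entrants, death_age))

  death <- cumsum(new_deaths)
  trace <- data.frame(cycle = 0:n, pfs_on = pfs_on, pfs_off = pfs_off,
                      pd = pd, death = death, new_deaths = new_deaths)
  class(trace) <- c("cohort_trace", "data.frame")
  validate_trace(trace)
  trace
}

validate_trace <- function(trace, tol = 1e-9) {
  occ <- as.matrix(trace[, c("pfs_on", "pfs_off", "pd", "death")])
  if (any(!is.finite(occ))) {
    stop("cohort trace contains non-finite occupancy", call. = FALSE)
  }
  if (any(occ < -tol)) {
    stop("cohort trace contains negative occupancy", call. = FALSE)
  }
  if (any(abs(rowSums(occ) - 1) > tol)) {
    stop("cohort occupancy rows do not sum to one", call. = FALSE)
  }
  if (any(diff(trace$death) < -tol)) {
    stop("death occupancy is not monotone", call. = FALSE)
  }
  invisible(trace)
}

#' Undiscounted life-years of a cohort trace
#'
#' Sums the alive proportion at the start of each cycle times the cycle length
#' in years.
#'
#' @param trace A [run_cohort()] trace.
#' @param config The configuration it was run under.
#' @export
life_years <- function(trace, config) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- n_cycles(config)
  alive <- trace$pfs_on + trace$pfs_off + trace$pd
  w <- accrual_weights(alive, n, config$half_cycle_correction)
  sum(w) * config$cycle_days / 365.25
}

# Occupancy weights used for cost/QALY accrual: state at the start of each of
# the n cycles (rows 0..n-1); with the half-cycle correction, the mean of the
# start- and end-of-cycle occupancies.
accrual_weights <- function(x, n, half_cycle = FALSE) {
  if (half_cycle) (x[1:n] + x[2:(n + 1)]) / 2 else x[1:n]
}

#' Export a cohort trace as CSV
#'
#' @param trace A [run_cohort()] trace.
#' @param path Output file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
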