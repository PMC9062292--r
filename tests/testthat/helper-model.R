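# shared fixtures built in code

os_base <- weibull_params(0.004716, 1.533854)
pfs_base <- weibull_params(0.003867, 2.335407)

base_cfg <- default_config()

# config with a short horizon for cheap sweeps
short_cfg <- default_config(horizon_years = 3)

# independent slow-path cohort engine: explicit per-entrant-cohort loop over
# progressive-disease age, used as an oracle against the convolution engine
loop_cohort <- function(arm, config) {
  n <- n_cycles(config)
  q_prog <- wb_cond_exit_prob(arm$pfs, seq_len(n))
  q_death <- wb_cond_exit_prob(arm$os, seq_len(n))
  on_tx <- seq_len(n) <= arm$tx_cycles
  q_exit_on <- ifelse(on_tx, 1 - (1 - q_prog) * (1 - q_death), q_prog)
  p_disc <- ifelse(on_tx, arm$p_discontinue_ae, 0)
  pfs_on <- numeric(n + 1); pfs_off <- numeric(n + 1); pfs_on[1] <- 1
  entrants <- numeric(n)
  for (t in seq_len(n)) {
    entrants[t] <- pfs_on[t] * q_exit_on[t] + pfs_off[t] * q_prog[t]
    stay_on <- pfs_on[t] * (1 - q_exit_on[t])
    pfs_on[t + 1] <- stay_on * (1 - p_disc[t])
    pfs_off[t + 1] <- pfs_off[t] * (1 - q_prog[t]) + stay_on * p_disc[t]
  }
  q_age <- wb_cond_exit_prob(arm$os, seq_len(n + 1))
  pd <- numeric(n + 1); new_deaths <- numeric(n + 1)
  for (s in seq_len(n)) {          # cohort entering PD during cycle s
    mass <- entrants[s]
    if (mass == 0) next
    surv <- mass
    for (tt in s:n) {              # age a = tt - s + 1 during cycle tt
      a <- tt - s + 1
      died <- surv * q_age[a]
      new_deaths[tt + 1] <- new_deaths[tt + 1] + died
      surv <- surv - died
      pd[tt + 1] <- pd[tt + 1] + surv
    }
  }
  data.frame(cycle = 0:n, pfs_on = pfs_on, pfs_off = pfs_off, pd = pd,
             death = cumsum(new_deaths), new_deaths = new_deaths)
}
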