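---
title: "A Markov cohort model for first-line bevacizumab-biosimilar therapy in nonsquamous NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for first-line bevacizumab-biosimilar therapy in nonsquamous NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bevcea)
```

## The decision problem

`bevcea` implements a cost-effectiveness evaluation of first-line LY01008 — a
bevacizumab biosimilar — combined with carboplatin/paclitaxel against
carboplatin/paclitaxel alone, in Chinese patients with advanced or recurrent
nonsquamous non-small-cell lung cancer, from the healthcare-system
perspective. The comparison is indirect: the chemotherapy arm's survival
curves come from a large Chinese trial of bevacizumab, and the biosimilar's
effect enters as network-meta-analysis hazard ratios (OS 0.654, 95% CI
0.302–1.410; PFS 0.405, 95% CI 0.078–2.160) applied to those curves.

The model is a deterministic cohort simulation over four states —
progression-free on first-line treatment (PFS-on), progression-free after
AE-related treatment discontinuation (PFS-off), progressive disease (PD) and
death — on a 3-week cycle, over a 30-year horizon (521 cycles), with costs
and QALYs discounted at 5% per year and a willingness-to-pay threshold of
US\$33,438/QALY (three times 2020 per-capita GDP; CNY 230,635 at the
fixed reporting rate of 6.8974 CNY/US\$).

## Survival model and the cycle time unit

Both endpoints are Weibull, $S(t) = \exp(-\lambda t^{\gamma})$, with the
chemotherapy arm at $(\lambda_{OS}, \gamma_{OS}) = (0.004716,\,1.533854)$ and
$(\lambda_{PFS}, \gamma_{PFS}) = (0.003867,\,2.335407)$, and the per-cycle
exit probability
$P(t) = 1 - \exp\!\left[\lambda (t-1)^{\gamma} - \lambda t^{\gamma}\right]
      = 1 - S(t)/S(t-1).$
The combination arm multiplies $\lambda$ by the hazard ratio and keeps
$\gamma$; hazard ratios therefore compose multiplicatively and a ratio below
one dominates the reference curve at every time.

Time is indexed in 3-week model cycles. This is forced by the parameters
themselves: they imply a median OS of 25.9 *cycles* (17.9 months) and a
median PFS of 9.2 cycles (6.4 months), matching the reference-arm trial
medians only under this unit.

```{r medians}
wb_median(weibull_params(0.004716, 1.533854)) * 21 / 30.4375  # months
wb_median(weibull_params(0.003867, 2.335407)) * 21 / 30.4375
```

## Transition structure

The printed formulas give two curves but label $S(t)$ itself "the transition
probability from PFS to death", which cannot be a per-cycle probability, so
the state-transition wiring is genuinely under-determined. We resolved it by
requiring the model to reproduce the published arm-level totals, which
constrain the structure tightly:

* Any wiring in which every living state faces the OS conditional
  probability by model time makes total cohort survival equal $S_{OS}(t)$
  exactly. That bounds the chemotherapy arm's *undiscounted* QALYs at about
  1.46 (mean OS $= \Gamma(1+1/\gamma)\lambda^{-1/\gamma} \approx 29.7$
  cycles $\approx 1.70$ years, times a utility of at most 0.856), below the
  published *discounted* 1.63. Such readings were rejected as infeasible.
* The published totals are matched when overall survival governs the
  post-progression phase: every PFS exit enters PD, and PD survival follows
  the arm's OS Weibull with the clock restarted at progression (deaths occur
  from PD only, with a patient's first post-progression death risk falling in
  the cycle of progression).
* While a patient is receiving first-line drug (the whole of PFS-on in the
  combination arm, the first `max_chemo_cycles` cycles in the
  chemotherapy-only arm), the OS-derived hazard competes with the progression
  hazard as a PFS exit,
  $q_{exit}(t) = 1 - (1 - q_{PFS}(t))(1 - q_{OS}(t))$; off treatment only
  the progression hazard applies. The AE disutility and the per-cycle
  AE-discontinuation probability are likewise confined to the on-treatment
  window.

AE-related discontinuation moves on-treatment stayers to PFS-off
(progression-free utility without the treatment disutility, no drug cost,
follow-up continues); the substate is absorbing until progression.

Three structural quantities are not printed at all and were fixed **once** by
calibration against the published base-case table, then frozen across every
analysis, and are echoed in all output metadata:

| setting | calibrated value | grid searched |
|---|---|---|
| chemotherapy induction cycles | 5 | 4, 5, 6 |
| carboplatin target AUC | 5 | 5, 6 |
| P(active subsequent therapy in PD) | 0.6425 | \[0, 1\] step 0.0025 |

With these frozen, the ten published base-case and scenario values reproduce
within 2.2% (incremental QALYs 0.490 vs 0.48; chemotherapy arm QALYs 1.630).

## Costs

Drug acquisition is anthropometry-dependent for the base-case patient (65 kg,
1.72 m², creatinine clearance 70 ml/min): LY01008 15 mg/kg (975 mg),
paclitaxel 175 mg/m² (301 mg), carboplatin by the Calvert formula,
AUC × (CrCl + 25). Prices are per small unit (US\$24.99 per 15 mg, 57.51 per
175 mg, 1.37 per 6 mg), which indicates per-mg proration; `billing = "linear"`
prorates and `"vial"` rounds units up. Carboplatin/paclitaxel stop at the
induction cap; LY01008 continues as maintenance until progression or
discontinuation. The 7.5 mg/kg scenario halves only the LY01008 dose, so the
base-to-scenario cost difference equals exactly half the discounted LY01008
acquisition cost — an identity the tests assert.

State costs per cycle: routine follow-up US\$55.60 in either PFS substate; in
PD, active subsequent therapy (US\$854.05) for the calibrated proportion of
patients and best supportive care (US\$337.50) for the rest; one terminal
cycle of palliative care (US\$2,627.80) per death. Frequency-weighted
aggregate AE treatment costs (US\$1,025.82 combination, 745.01 chemotherapy)
are charged once, to the whole cohort, in the first cycle — trial AE
frequencies are per treatment course, not per cycle.

## Discounting and QALYs

Discounting is continuous-time, $(1+r)^{-t \cdot 21/365.25}$, so one year of
cycles discounts by exactly $1/1.05$. Recurring costs and utilities accrue on
start-of-cycle occupancy (the cycle-0 row counts; no half-cycle correction by
default, switchable); event costs — the AE lump and palliative care — are
discounted at the end of the cycle in which they occur. QALYs weight
person-time by 0.856 in PFS (minus the arm's AE disutility, 0.061 or 0.080,
while on treatment) and 0.768 in PD. With a zero discount rate and all
utilities 1, QALYs equal undiscounted life-years exactly.

## Sensitivity analyses

**One-way (DSA).** Hazard ratios, utilities, disutilities and discontinuation
probabilities move across their 95% CIs, the discount rate across 0–8%, all
other parameters ±50%; Weibull parameters stay fixed. The two-arm model is
rerun at each limit and entries are ranked by ICER spread. The published
ranges are evaluated as printed even where the PFS-utility lower limit
(0.718) dips below the base PD utility (0.768) — the utility ordering is a
sampling constraint, not a range edit. The nivolumab unit price is carried
for completeness but the PD state is costed with the aggregate
subsequent-therapy cost, so its spread is zero.

One published claim does not survive reproduction: that patient weight and
the LY01008 unit price are the *only* lower-limit runs crossing below the
WTP threshold. Reproducing the published totals forces the combination arm's
survival gain to accrue in PD, and a PD cycle costs at most
US\$854.05 against $0.768 \times 0.0575$ QALYs — about US\$19,300/QALY,
well under the threshold. The OS hazard ratio's lower limit (0.302), which
more than doubles post-progression survival, therefore *must* drive the ICER
below the threshold (it lands near US\$28,800/QALY) in any model consistent
with the published totals. The corresponding acceptance test asserts the
published claim verbatim and fails, documenting the discrepancy rather than
hiding it.

**Probabilistic (PSA).** 1,000 Monte-Carlo draws; beta distributions
(method-of-moments on mean and $sd = (high - low)/3.92$) for probabilities,
utilities and disutilities, gamma for costs, normal for anthropometrics, and
— following the printed distribution table — plain normal for the hazard
ratios. Draws invalid for the model (non-positive hazard ratios or
anthropometrics, PD utility above PFS utility) are rejected and the vector
redrawn jointly, up to 100 attempts, never clamped; rejection counts are
reported. A log-normal hazard-ratio option (`hr_psa_dist = "lognormal"`)
exists but is not the default: truncating a plain normal at machine epsilon
would pile the ~22% negative mass of the PFS hazard ratio at zero, while the
log-normal understates the probability of cost-effectiveness; rejection
sampling of the printed normal reproduces the published 23.5% probability at
the threshold (we obtain 21–24% across seeds). A consequence of rejection
is that sampled hazard-ratio means sit at the truncated-normal expectation
rather than the base value, and the model's nonlinearity makes the mean
incremental QALY (~0.69) exceed the deterministic 0.49; tests therefore
check sampler moments, not model-output means. One master seed spawns
per-draw substreams, so draw $i$ is identical regardless of how many draws
are requested.

## Synthetic patient data

The generator exists so the survival-fitting pathway is testable without any
external data: inverse-CDF Weibull draws $t = (-\ln U/\lambda)^{1/\gamma}$ on
the cycle grid, arm-specific scales via the hazard ratios, progression-free
time taken as the minimum of independent progression and survival draws
(which enforces PFS ≤ OS per patient), and administrative censoring.
By default the uniforms are jittered-stratified in random order: each draw is
marginally uniform, but the ensemble is balanced, so a 10,000-patient
refit recovers the generating parameters to a fraction of a percent and
parameter-recovery tests probe the estimator rather than draw luck. (With
plain iid draws, `method = "iid"`, the scale estimate has a ~6% relative
standard error under 30% censoring at this size, which would make a 5%
recovery tolerance a coin flip.) The generator does **not** emulate real
trial data in other respects: progression and death times are independent
copies rather than a clinically coupled pair, and there is no recruitment,
loss to follow-up or covariate structure — so passing recovery tests
validates the fitting code, not the realism of any dataset.

Weibull fitting maximises the right-censored log-likelihood
$\sum_{events}\log h(t_i) + \sum_{all}\log S(t_i)$ by BFGS on
log-parameters (positivity by construction, relative tolerance $10^{-8}$),
with delta-method standard errors from the observed information; at least two
events are required. Tests cross-check the estimates, standard errors and
log-likelihood against an independent parametric survival fitter.

## Numerical implementation

PD occupancy is the discrete convolution of progression entrants with the
restarted OS survival curve; the engine evaluates it as a lower-triangular
Toeplitz matrix product (exact to floating point, fast enough that a full
two-arm run takes milliseconds, the DSA seconds, and the 1,000-draw PSA well
under a minute). Tests verify the engine against an explicit per-cohort loop
and, over short horizons, against an age-expanded transition-matrix product,
both at $10^{-12}$; occupancy rows sum to one at $10^{-12}$ over all 521
cycles and the death column is monotone. Degenerate inputs fail loudly:
negative times, non-positive hazard ratios, probabilities outside \[0, 1\],
all-censored fits.

## Problem sizes

The shipped analyses use the full 521-cycle horizon, 1,000 PSA draws, a
42-run DSA, and 10,000-patient synthetic cohorts for recovery checks — the
same sizes as the published analysis where one is stated, and comfortable
desk-scale sizes where not.

## Known limitations

* The transition wiring is a calibrated reconstruction; other wirings with
  additional free parameters could fit the same totals differently. All
  structural choices are config-exposed and echoed in output metadata.
* Post-progression survival restarting the OS clock at progression is a
  strong assumption (it makes total survival exceed the OS curve read from
  baseline); it is, however, the only reading we found that reproduces the
  published QALY levels.
* The currency conversion is a fixed reporting rate; CNY figures are
  derived, never modelled.
* The DSA-uniqueness discrepancy described above is inherent to the published
  inputs, not tunable away.
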