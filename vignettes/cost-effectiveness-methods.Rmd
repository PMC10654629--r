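---
title: "Model and methods: serplulimab + chemotherapy for PD-L1-positive advanced ESCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esccea)
```

## The decision problem

Serplulimab added to cisplatin/5-FU improves progression-free survival
(PFS) and overall survival (OS) in previously untreated PD-L1-positive
advanced esophageal squamous cell carcinoma, at a per-cycle drug cost an
order of magnitude above the chemotherapy backbone. The package asks the
standard health-technology-assessment question: per quality-adjusted
life-year (QALY) gained, what does the addition cost, and is that below
the willingness-to-pay (WTP) threshold of $37,663.26/QALY (three times
China's per-capita GDP)?

## Model structure

Three mutually exclusive health states — progression-free (PFS),
progressed disease (PD), dead — in a cohort starting entirely
progression-free. Occupancy is computed by partitioned survival from two
Weibull curves per arm, $S(t) = \exp(-\lambda t^\gamma)$ with $t$ in
months:

$$\mathrm{pfs}(t) = S_{PFS}(t), \qquad
  \mathrm{death}(t) = 1 - S_{OS}(t), \qquad
  \mathrm{pd}(t) = S_{OS}(t) - S_{PFS}(t).$$

The curves are fitted independently per arm, so nothing forces
$S_{OS} \ge S_{PFS}$ everywhere; where the implied PD occupancy would be
negative the model clamps it to zero and assigns the mass to death,
keeping every row summing to one. The shipped parameter sets never
trigger the clamp inside the 120-cycle horizon, but the rule matters for
user-supplied fits (the affected cycles are recorded on the trace).

An explicit $3\times 3$ transition matrix is not needed: the source
analysis specifies only the two fitted curves plus the per-cycle exit
probability $P(t,u) = 1-\exp\{\lambda(t-u)^\gamma - \lambda t^\gamma\}$,
and the partitioned-survival occupancy is the unique one consistent with
both. The split of PFS exits between progression and death, which the
curves alone cannot identify, is thereby defined residually.
`trace_transition_check()` verifies the identity
$\mathrm{pfs}(t-1)-\mathrm{pfs}(t) = P(t,1)\,\mathrm{pfs}(t-1)$ to
machine precision:

```{r}
tr <- build_trace(weibull_params(0.0594, 1.275),
                  weibull_params(0.0119, 1.478))
trace_transition_check(tr)$max_discrepancy
```

## Accrual conventions

Costs accrue per monthly cycle: all treatment-phase components (drug,
chemotherapy, antiemetics, tests, adverse-event management,
hospitalization) while progression-free, the subsequent-therapy cost
while progressed, with no cap on treatment duration. Utilities (0.68
PFS, 0.42 PD, 0 dead) are annual-scale, so a cycle contributes
occupancy × utility / 12 QALYs. Both streams are discounted at
$(1+r)^{-t/12}$ with $r = 0.05$.

**Half-cycle correction.** State membership is known at cycle
boundaries; events happen in between. The package defaults to
trapezoidal accrual (half weight on the cycle-0 and terminal states,
`half_cycle_correction = TRUE`), the convention TreeAge applies, and
back-calculation confirms it: with the shipped parameters the corrected
model gives 0.781/0.619 QALYs and \$43,471/\$13,910 for the CPS≥1 arms,
within 0.3% of the published 0.78/0.62 and \$43,427/\$13,880, whereas
cycle-end accrual understates QALYs by ~0.03 and costs by ~5%. The
switch is exposed in `model_settings()` for users who want the
uncorrected sum.

## Parameters

All parameters ship in `inst/extdata/default_config.yaml`: per-cycle
costs in USD (converted at \$1 = ¥6.77; chemotherapy dosed at BSA
1.72 m², weight 65 kg), utilities, and Weibull $(\lambda, \gamma)$ per
endpoint, arm and PD-L1 CPS stratum (CPS≥1, 1≤CPS<10, CPS≥10). Two
published inconsistencies are worth knowing about:

- the CPS≥10 chemotherapy-arm Weibull parameters imply a median OS near
  9 months and chemotherapy-arm QALYs near 0.81, irreconcilable with the
  trial's reported subgroup medians (13.9 months) and the published
  0.62 QALYs for that cell. The values are shipped as printed, flagged
  in the config comments; full-model output for that stratum should not
  be compared against the published table. The stratum's incremental
  arithmetic (ICER \$127,996.45, INMB −\$26,196.62) is internally
  consistent and is what the tests check.
- two published incremental net monetary benefits equal $-\Delta C$
  rather than $\Delta E \cdot \mathrm{WTP} - \Delta C$. The package
  always applies the formula (e.g. −\$23,521.76 for CPS≥1 from the
  published increments), and the test suite asserts the discrepancy
  rather than reproducing it.

## Sensitivity analyses

One-way analysis varies each cost component, each arm's joint
treatment-phase cost (the "cost of PFS" tornado bar), and both
utilities by ±20%, re-running the full model twice per parameter and
ranking by the induced INMB range. Survival parameters stay fixed, as
in the source analysis.

The probabilistic analysis draws every nonzero cost from a
moment-matched gamma and the two utilities from moment-matched betas
(shared across arms within a draw, with the PD utility capped at the
PFS utility draw-wise), again with survival fixed. No standard errors
are published, so each parameter's SE is set to 20% of its mean —
mirroring the one-way span, a common convention when dispersion is
unreported — and exposed as `se_fraction`. Because the survival curves
are fixed and accrual is linear in costs and utilities, each draw
reduces to a weighted sum over the precomputed traces; 1000 iterations
take well under a second. The CEAC grid defaults to \$0–\$250,000 in
\$2,500 steps, covering the \$100k/\$200k thresholds discussed for this
setting.

## Curve reconstruction and fitting

The front end inverts a digitized KM curve into pseudo individual
patient data in the interval style of Hoyle-type reconstruction: event
counts are chosen per digitized point so the recomputed product-limit
curve tracks the digitized drops; censoring is spread uniformly within
each numbers-at-risk interval so the at-risk counts match, or — without
a risk table — placed entirely at the end of follow-up, which turns a
terminal plateau into censored records. Fitting maximises the
right-censored Weibull log-likelihood in $(\log\lambda, \log\gamma)$
space (unconstrained and scale-stable), initialised from least squares
on $\log(-\log S)$ vs $\log t$; standard errors are delta-method
transforms of the inverse observed information. A round-trip tolerance
of 0.02 absolute survival is used in tests, matching the noise floor of
careful plot digitization.

The source analysis does not state whether its curve fits used the
reconstructed-IPD likelihood or least squares on the curves; the two
give similar but not identical parameters. The package implements the
likelihood route and treats the published $(\lambda,\gamma)$ as
authoritative inputs to the economic model, so this choice affects only
user-run refits.

## The synthetic trial generator

`simulate_trial()` emulates the source trial's design: two arms under
2:1 allocation (368/184 by default), Weibull event times per endpoint,
administrative censoring at 15 months of follow-up. PFS and OS are
coupled through a shared latent death time — death times come from the
OS Weibull, a latent progression time carries the residual cumulative
hazard $H_{PFS}-H_{OS}$ (numerically inverted), and PFS is the minimum
of the two — so both marginals are exact while no subject progresses
after dying. This requires the PFS cumulative hazard to dominate the OS
one, which holds for all shipped parameter sets over any practical
horizon and is checked at simulation time. `make_digitized_fixture()`
then emulates plot digitization: survival read on a uniform time grid
with Gaussian error (default SD 0.005, a typical extraction error),
clamped and made monotone by a running minimum.

What the generator does *not* emulate: dependent (drop-out) censoring,
non-proportional late-crossing hazards, interval-censored progression
assessment, or digitizer time-axis error. Passing the end-to-end
recovery tests therefore shows the pipeline is internally consistent
under clean trial-like conditions, not that reconstruction from real,
imperfectly digitized figures is unbiased. One known small bias is
inherent to the method: events pooled at digitized grid points are
recorded slightly late, which at long follow-up and large $n$ can shift
$\hat\lambda$ by a fraction of a standard error.

## Numerical choices and problem sizes

- Rounding in reconstruction uses nearest-integer event counts; the
  censor-count adjustment loop runs at most 25 iterations (it settles in
  2–3).
- MLE optimisation: BFGS, relative tolerance $10^{-12}$; the fixed-shape
  case uses the closed form $\hat\lambda = d/\sum t^\gamma$.
- Degenerate inputs fail loudly: all-censored fits, fewer target records
  than survival drops, infeasible beta moments, negative times/rates.
- Tests exercise the fitters at $n \le 2000$ and the end-to-end recovery
  at $n = 500$ with 50 digitized points — sizes chosen to keep each
  Monte Carlo check's sampling error well inside its tolerance while the
  whole suite runs in seconds.

## Limitations

Beyond the generator caveats above: the model inherits the source
analysis's structural assumptions (homogeneous cohort, no treatment-
duration cap, subsequent-therapy costing collapsed to a per-cycle PD
cost, utilities constant within states); only direct medical costs are
counted; and the assistance-programme (drug-donation) scenario depends
on dose-rounding and block-timing assumptions that are configurable but
not uniquely determined, so it is best read qualitatively — lowering the
effective drug price lowers the ICER, without bringing it below the
threshold under any schedule shipped here.
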