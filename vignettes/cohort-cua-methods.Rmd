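---
title: "Methods: a Markov cohort cost-utility model for glaucoma therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model for glaucoma therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaucua)
```

## The decision problem

`glaucua` models the cost-utility of a latanoprost cationic emulsion
(arm A) against standard latanoprost (arm B) in open-angle glaucoma /
ocular hypertension (OAG/OHT) patients with concomitant ocular surface
disease (OSD). The emulsion's hypothesised advantages are a lower annual
probability of OSD, higher treatment adherence in the milder disease
stages, and slightly higher mid-stage utilities; its monotherapy per-diem
is higher (EUR 0.30 vs 0.24). The model asks whether the QALY gains justify
the cost difference against a willingness-to-pay (WTP) of EUR
30,000-50,000 per QALY.

## Model structure

Seven mutually exclusive states: OAG/OHT stages 0 (ocular hypertension)
through 5 (end-stage/blind) plus absorbing death. Cohorts of 1000 notional
patients enter stage 0 at age 47.31 and run for 5 annual cycles of 365.25
days. Disease can only remain stable or progress; backward transitions are
structurally absent (upper-triangular transition rows, validated).

**Competing risks.** Elicited disease rows exclude death, so each cycle
applies mortality first and disease movement conditionally on survival:
`P(s -> death) = q(age, sex mix)` and `P(s -> s') = (1 - q) t[s, s']`. This
keeps every row stochastic for any `q` and is a modelling decision of this
package: whether the original elicitation was conditional on survival is
not documented, and the alternative (unconditional rows renormalised) is
not expressible without extra assumptions. Mortality is interpolated
linearly between integer ages within each sex and mixed by the cohort's
female fraction (0.50); age advances one year per cycle from the fractional
entry age. Death is the only arm-invariant pathway: no stage-specific
excess mortality is modelled, consistent with near-identical death counts
in both arms.

**Person-time and half-cycle correction.** Accrual is attributed to the
state occupied at cycle start. Survivors of a cycle contribute one year;
within-cycle decedents contribute half a year in their starting state (the
half-cycle correction, on by default), or nothing with the correction off.
The decedents' six months must be located somewhere; the starting state is
the only defined location under start-state attribution.

**Outcomes.** Life-years are person-years per patient. QALYs weight
person-time by the effective utility `u[arm, stage] + p_osd[arm] * d_osd`,
floored at zero: one arm-level annual OSD probability (0.762 / 0.837)
multiplies one shared disutility (-0.120), with no stage interaction.
Utility of death is 0.

**Costs.** Four categories, all per patient:

* *diagnosis* — one-time work-up at entry (cycle 1, undiscounted), using
  the stage-0 volume column since the whole cohort enters there;
* *medication* — monotherapy per-diem x 365.25 days x the stage- and
  year-specific adherence probability. Adherence scaling is the package's
  reading of how adherence enters the arithmetic: published 5-year
  medication totals are roughly 0.74 / 0.65 of full-adherence cost, and no
  other mechanism is documented. Adherence deliberately does **not**
  modify transitions or utilities, which were elicited separately per arm;
* *add-on therapies and follow-up* — annual volumes of visits/tests plus
  prescription-probability-weighted add-on drops
  (probability x per-diem x 365.25);
* *OSD management* — visits, Schirmer testing and OSD drugs
  (preservative-free lubricant at 365.25 days/year; ciclosporin courses at
  90 days/year, a package assumption keeping its EUR 3.67 per-diem from
  dominating the category).

**Discounting.** All streams are discounted at 2.5 %/year with factor
`(1+r)^-(t-1+offset)`. The default `offset = 0` leaves the first year
undiscounted — the common cohort-model convention; the switch to
`offset = 1` is exposed in `econ_settings()` because the original
convention is not documented.

## Parameter uncertainty

Every non-fixed parameter carries a method-of-moments distribution chosen
by support: beta for probabilities and utilities, gamma for resource
volumes and the OSD disutility (fitted to the magnitude and negated, since
gamma support is positive), normal for procedure unit costs (truncated at
zero by resampling rather than clipping, to avoid a point mass), and
Dirichlet for transition rows (`alpha = p x ess`). Where a standard error
is not elicited it is imposed as SE = CV x mean with a default CV of 0.2
(the originally used CV value is unpublished; 0.2 is a conventional
imposed dispersion and is configurable globally and per parameter). The
Dirichlet effective sample size defaults to 100 per row; the published
per-stage observation counts (about 400-1600) are a documented alternative
preset for analysts who prefer tighter rows. Drug posology and prices and
the discount rate are excluded from the PSA (regulator-set quantities);
the discount rate instead carries the prescribed one-way range 0-4.5 %.

One-way sensitivity analysis replaces one parameter at a time by its 95 %
CI or range bounds and recomputes the deterministic ICUR; entries are
ranked by bar width. A bound that lands in a dominance quadrant is
reported as a label, not a sign-flipped ratio. The PSA samples all
non-fixed parameters jointly (parameter-major order from one seeded
generator, so results are reproducible independent of any parallelism),
runs both arms, and summarises draws as quadrant counts on the
cost-effectiveness plane, percentile (2.5th/97.5th order-statistic,
linearly interpolated) confidence intervals, the CEAC
(`P(lambda dE - dC > 0)` per arm) and the CEAF (the acceptability of the
arm with the highest expected NMB; ties broken toward the cheaper arm).
Boundary draws with an increment exactly zero are assigned to the
positive-effect side and reported via a message.

## The synthetic generator

The elicited study inputs (transition rows, resource volumes, adherence
tables, life table) were never published. `generate_parameterset()`
produces complete parameter sets with the same structure, calibrated to
the published cohort-level anchors. Its defaults are fixed study
conditions, not tuning knobs:

* **Mortality**: flat annual `q = 1 - 0.885^(1/5) = 0.02414`, chosen so
  11.5 % of the cohort dies over 5 cycles (the published 114-115 deaths
  per 1000). A slope mode (exponentially increasing with age) exists for
  stress testing.
* **Stage-0 retention**: per-arm targets 0.66 (A) and 0.64 (B) — both
  within the published "approximately 65 %" band, ordered as the published
  traces (672 vs 649 per 1000). The conditional stay probability solves
  `[(1-q) p]^5 = target` in closed form
  (`calibrate_stay_probability()`).
* **Progression beyond stage 0**: a one-parameter family. Stage `s` leaves
  with probability `L_s = L_0 kappa^s` (capped at 0.95), spreading the
  leaving mass over more severe stages with geometric weights
  (decay 0.3 per additional stage). `kappa` is fitted by root-finding so
  arm A's stage-5 occupancy at the horizon is 5.5 per 1000 (published:
  5-6). Only endpoint occupancies are published, so a richer family would
  be unidentifiable.
* **Utilities**: both arms anchored at 0.900 (stage 0) and 0.790
  (stage 5); intermediate drops follow the published base-case profile,
  and arm B sits below arm A by the published gap profile
  (0, 0.007, 0.013, 0.013, 0.017, 0).
* **Adherence**: arm B declines from 0.68 by 0.02 per stage and 0.01 per
  year; arm A adds a uniform draw from 0.047-0.098 in stages 0-3 (the
  published contrast range) and is identical in stages 4-5.
* **OSD management gaps**: arm B exceeds arm A by stage-interpolated gaps
  within the published ranges (lubricant 5.88-11.34, ciclosporin
  4.31-5.39, Schirmer 7.29-9.57 percentage points).
* **Arm contrasts are generated on the probability scale**, matching how
  every published contrast is expressed.

Presets: `"paper-like"` (defaults above), `"null"` (arms exactly
identical — increments are exactly zero, used to test the accounting
identities), `"stress"` (doubled CV). All generation flows from one
integer seed through R's generator, so sets are bit-reproducible.

`base_case_parameters()` overlays the published fixture values (tariffs
with their printed CIs, utilities, disutility, OSD probabilities, drug
per-diems, economic settings) on a generated set and marks provenance
per field, so tests can distinguish published anchors from synthetic
completion.

### What the generator does and does not emulate

Generated sets reproduce the *structure* and the cohort-level anchors of
the study inputs, not their values: passing tests certify the engine,
accrual, and sensitivity machinery, and the qualitative result (arm A
gains QALYs at near-neutral cost), but no numerical equivalence with the
published ICUR or PSA scatter is claimed or targeted. In particular the
published PSA shows essentially all iterations favouring arm A, which
requires the (unpublished) correlation-free but much tighter elicited
dispersions; under this package's independent default dispersions the
probability that arm A gains QALYs is well below 1. Published trace SDs
(e.g. 672 +/- 215) are likewise not targeted: they cannot constrain the
generator without the unpublished parameter SEs.

## Numerical choices

* Transition rows must sum to 1 within 1e-9 at validation and 1e-12 after
  matrix construction; cohort mass is conserved to 1e-9 at every step.
* Effective utilities are floored at 0; infeasible beta SEs are clamped to
  99 % of the feasibility bound with a warning; Dirichlet draws renormalise
  exactly and keep structural zeros at zero.
* Degenerate comparisons: both increments zero reports "equivalent"; a
  zero QALY increment with nonzero cost reports dominance by cost sign; a
  ratio is only formed when increments share a sign.
* Reports round currency at 2 and QALYs/LYS at 3 decimals; all CSV output
  keeps full precision.

## Problem sizes

The test suite runs the enumeration oracle at 3 cycles (7^1+7^2+7^3
paths), the invariant battery over 100 generated seeds, moment-recovery
sampling at 10,000 draws, and percentile-CI coverage over 100 seeds of
1,000-iteration PSAs on a reduced-uncertainty model; the acceptance script
runs a 2,000-iteration PSA. These sizes were chosen to exercise every code
path at Monte Carlo errors small enough for the stated tolerances.

## Known limitations

No microsimulation mode, tunnel states, or time-varying disease rows
beyond mortality's age dependence; no stage-specific excess mortality; no
societal-perspective costs; no surgical or laser pathways (second-line
options excluded from scope); no correlation structure between sampled
parameters; no EVPI/EVPPI. The adherence-to-cost mechanism and the
diagnosis one-time/undiscounted treatment are package inferences from the
published totals, flagged here and switchable in the parameter set.
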