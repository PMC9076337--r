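# glaucua

Markov cohort cost-utility analysis for topical glaucoma therapies.

`glaucua` implements an early health-economic decision model comparing two
eye-drop strategies in patients with open-angle glaucoma or ocular
hypertension (OAG/OHT) and concomitant ocular surface disease (OSD): a
latanoprost cationic emulsion (arm A) against standard latanoprost (arm B),
from a health-system perspective. It is aimed at health-economics analysts
who want a scriptable, fully tested version of the usual spreadsheet cohort
model: transparent inputs, reproducible sensitivity analyses, and
machine-readable outputs.

## The model

Two cohorts of 1000 notional patients enter at age 47.31 in OHT (stage 0)
and move through 7 mutually exclusive states — disease stages 0–5 plus death
— over 5 annual cycles (365.25 days each). Backward transitions are
structurally impossible. Each cycle combines age- and sex-specific all-cause
mortality *q* with elicited disease rows *t* as competing risks:

```
P(s -> death) = q        P(s -> s') = (1 - q) t[s, s']   for s' >= s
```

Person-time is attributed to the state occupied at cycle start, with a
half-cycle correction: patients who die within a cycle accrue six months of
costs, life-years (LYS) and QALYs. QALYs weight person-time by stage utility
minus the expected OSD decrement `u + p_osd * d_osd` (with `d_osd = -0.120`
and arm-specific annual OSD probabilities 0.762 / 0.837). Costs accrue in
four categories — one-time diagnosis work-up, monotherapy medication
(per-diem x 365.25 x adherence), add-on therapies and follow-up, and OSD
management — and all streams are discounted at 2.5 %/year. The comparison is
summarised by

```
ICUR = (C_A - C_B) / (E_A - E_B)      NMB(lambda) = lambda * dE - dC
```

with dominance labels when the increments disagree in sign. One-way
sensitivity analysis pushes every parameter to its 95 % CI or range bounds
(tornado ranking); probabilistic sensitivity analysis draws all non-fixed
parameters from method-of-moments distributions (beta for probabilities and
utilities, gamma for volumes and the disutility magnitude, normal truncated
at zero for unit costs, Dirichlet for transition rows), and summarises
10,000 iterations as a cost-effectiveness plane, acceptability curves
(CEAC) and the acceptability frontier (CEAF).

The published inputs (unit costs, tariffs, utilities, OSD parameters) ship
as a fixture; the elicited fields that were never published (transition
rows, resource volumes, adherence, life table) are completed by a calibrated
synthetic generator (`generate_parameterset()`) and flagged
`provenance = "synthetic"`. See the methods vignette
(`vignettes/cohort-cua-methods.Rmd`) for every modelling choice.

## Worked example

```r
library(glaucua)
ps  <- base_case_parameters()   # published values + flagged synthetic completion
fit <- run_cua(ps)
print(fit)
```

```
Cohort cost-utility analysis (discounted, per patient)
            item        A A_share        B B_share difference
1      diagnosis  198.920    8.04  200.120    8.09     -1.210
2     medication  359.320   14.53  258.700   10.46    100.620
3 addon_followup 1319.380   53.36 1320.140   53.40     -0.760
4 osd_management  595.190   24.07  693.440   28.05    -98.250
5   overall_cost 2472.800  100.00 2472.400  100.00      0.400
6            lys    4.488      NA    4.488      NA      0.000
7          qalys    3.623      NA    3.577      NA      0.046

ICUR (deltaC/deltaQALY): 8.71 per QALY gained
```

Reading: over 5 years the emulsion arm costs €0.40 more per patient — its
higher medication cost (+€100.62, driven by the €0.30 vs €0.24 per-diem and
better adherence) is almost exactly offset by cheaper OSD management
(−€98.25) — while gaining 0.046 QALYs from lower OSD exposure and small
mid-stage utility advantages, for an ICUR of €8.71 per QALY: far below a
€30,000 willingness-to-pay threshold. Sensitivity analyses follow the same
object:

```r
tor <- run_owsa(ps)            # tornado table, widest bars first
psa <- simulate(fit, nsim = 10000, seed = 1)
summary(psa, wtp = 30000)
plot(psa, "ceac")
```

A thin command-line wrapper over the same functions lives at
`inst/cli/glaucua.R` (`run`, `owsa`, `psa`, `synth`, `validate`).

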