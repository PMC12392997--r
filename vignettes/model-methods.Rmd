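---
title: "Methods: a Markov cohort cost-utility model for combined upper-GI endoscopic screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model for combined upper-GI endoscopic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugcscreen)
```

## Scope and model structure

`ugcscreen` evaluates combined endoscopic screening for esophageal, cardia
and gastric cancer with a deterministic annual-cycle Markov cohort model: a
closed cohort enters at age 40 and is followed to age 80, and state
occupancy evolves as fractions under a stochastic transition operator.
Cohort-level expectation is the estimand throughout; there is no
microsimulation, so identical inputs always yield bit-identical traces.

The core state space has 16 disease states on three organ ladders —
esophagus (mD, MD, SD/CIS, early, advanced), cardia (IM, LGIN, HGIN,
early, advanced) and gastric (CAG, IM, LGIN, HGIN, early, advanced) —
plus a healthy state, a post-endoscopic-treatment state, and absorbing
cancer-death and other-death states. Before intramucosal carcinoma,
lesions may regress (to a lower grade or to healthy); from early cancer
onward, transitions are forward-only. The engine expands this space
internally:

* **Tunnel states.** Each advanced-cancer state is split into six
  duration-indexed copies. Years 1–5 after entry carry an annual death
  probability `q = 1 − S₅^(1/5)` derived from the stage's 5-year survival
  under a constant-hazard split; year 6+ holds the year-1 value. A cohort
  forced into advanced cancer reproduces `S₅` after five cycles to 1e-6
  (asserted in the tests).
* **Surveillance states.** Follow-up arms track screen-detected
  lower-grade lesions in parallel surveillance copies that share the
  underlying state's transitions and utilities; progression to advanced
  cancer exits surveillance (clinical presentation), regression to
  healthy discharges it.

This gives 48 engine states; users only see the 20 core states.

## Within-cycle ordering

The sequencing inside a cycle is fixed for reproducibility, since a
cohort-level model must commit to one ordering:

1. screening round (if the attained age is on the strategy's schedule),
2. diagnosis costing of newly advanced mass (below),
3. follow-up surveillance round (follow-up arms, annually after the first
   screening age),
4. natural-history transition, composed as: other-cause death first at the
   attained-age probability, then cancer death (age-indexed for early
   cancer, duration-indexed for advanced), then disease transitions on
   the survivors.

QALYs accrue on the start-of-cycle occupancy; costs accrue on events
within the cycle; both are discounted by `(1 + r)^(−t)` with `t = 0` at
model entry. No half-cycle correction is applied by default
(`options$half_cycle` enables occupancy averaging); the default keeps
cycle sums exactly auditable against hand calculations.

## Screening, detection and cost routing

A fraction `c_s` of the live, undiagnosed cohort attends each scheduled
round (compliance is an independent per-round attendance fraction, not a
persistent attender subgroup — the natural reading for a fraction-flow
cohort given a single published rate). Within attenders, lesion states
are detected with sensitivity `Se`; healthy and post-treatment attenders
are false-positive with probability `1 − Sp`. False positives incur no
extra cost by default (endoscopy with biopsy is treated as confirmatory
in-session); `options$fp_cost` attaches a per-false-positive cost if
wanted.

Detection management mirrors the structure of the published cost table,
which prices exactly three treated entities per organ — an endoscopically
treatable high-grade precancer (SD/CIS grade), early cancer, and advanced
cancer with separate screen-detected and clinically-detected rates:

* SD/CIS (esophagus) and HGIN (cardia, gastric) → endoscopic treatment at
  the organ's SD/CIS-grade cost, transition to post-treatment.
* Early cancer → curative endoscopic resection cost, post-treatment.
* Advanced cancer → screen-detected treatment cost; the mass stays in its
  tunnel.
* Lower grades (mD, MD, IM, LGIN, CAG) → annual surveillance in follow-up
  arms (each surveillance endoscopy costs one screening unit, attended at
  `c_f`), untouched otherwise.

**Treatment-cost timing.** Mass entering an advanced state is undiagnosed
for one cycle. If a screening round falls in that cycle, a fraction
`c_s·Se` is screen-detected (cheaper treatment rate) and the remainder
presents clinically (clinical rate); otherwise all of it presents
clinically. Early-cancer and high-grade-precancer treatment costs accrue
only on screen or follow-up detection — consistent with the cost table
printing a detection-route split only for advanced cancer, i.e. with
early disease that never surfaces clinically before progressing. Each
unit of advanced mass is costed exactly once.

Screening stops after age 70 although the model runs to 80; follow-up
surveillance continues to the horizon (lesions under surveillance are not
discharged at 70; the interval is `options$surveillance_interval`, 1 year
by default, a conventional surveillance recommendation).

## Parameters

All tunables carry a base value, a deterministic range and a sampling
family (`parameter_table()` lists them). The headline values: screening
compliance 0.60 (0.30–0.80, triangular), follow-up compliance 0.75
(0.50–0.90), sensitivity 0.96 (0.90–0.99), specificity 0.90 (0.80–0.95),
discount rate 0.03 (0.02–0.05), screening cost ¥651.36 per endoscopy
(gamma), state utilities 0.724–0.969 (beta/triangular, clamped at 1.0
where ranges touch 1.000), treatment costs ¥21,951–¥76,138 by organ,
stage and detection route (gamma). Cohort size 100,000, ages 40–80,
willingness-to-pay ¥70,653/QALY (one-time per-capita GDP, 2019).

**Beta/gamma recentering.** The published beta/gamma parameter pairs are
inconsistent with their own base-case values under any plain reading
(e.g. β(0.929, 0.145) has mean 0.865, not the printed 0.921; γ(2.16,
0.003) has mean 720, not 651.36). The default `beta_gamma_mode =
"recentered"` therefore keeps the printed family but refits its
parameters by method of moments so the sampling mean equals the base
value, reading the printed range as ≈ mean ± 2 SD; `"raw"` mode uses the
printed pairs verbatim. Recentering keeps the probabilistic analysis
centered on the deterministic base case, which is what the published
analysis evidently intends.

**Probability conversions.** Multi-year transition probabilities are
annualised by constant-hazard compounding `p₁ = 1 − (1 − p_T)^(1/T)`
(round-trip exact to 1e-12); mortality series supplied as rates convert
via `p = 1 − exp(−rate)`. Both are the standard conversions, chosen
because the source material states only that a conversion is performed.

**Mortality mapping.** Three series enter the model: all-cause-excluding-
UGC mortality (applied competitively to every live state), age-indexed
UGC mortality (applied to early-cancer states, rising with age), and the
duration-indexed advanced series. The assignment of the age-indexed UGC
series to early-cancer states is this package's choice; the source
material names the three inputs without printing their state mapping.

## The synthetic natural history

The transition probabilities, initial lesion prevalences and yearbook
mortality tables behind published analyses live in non-public
supplementary material, so `synth_parameter_set()` generates seeded
stand-ins and combines them with the published parameter values. The
generator emulates: three organ ladders with forward intensities of
2–12%/year and regressions of 2–5%/year among pre-intramucosal grades;
onset probabilities of 0.7–1.4%/year into the first grade of each ladder
(a high-incidence-region level); early→advanced progression 35%/year;
an initial distribution with ≈ 98% healthy and grade-decreasing lesion
fractions (emulating lesion detection in a 40–44-year-old population,
with no prevalent advanced cancer); exponential-in-age other-cause
mortality from 3/1,000 at 40 to 6.5/100 at 80; and 5-year survival of
0.20 for advanced cancer at every site. Each edge gets multiplicative
lognormal jitter (SD 0.1) under the spec's seed, so seeds produce
distinct but structurally identical histories.

Under these defaults the no-screening arm accumulates roughly 4,700–4,900
cancer cases per 100,000 over the 40-year horizon (computed by the test
suite and the acceptance script), inside the 2,000–15,000 band that
brackets published registry-calibrated figures. The synthetic tables make
no claim of clinical accuracy: passing tests demonstrate that the
*machinery* — conservation, tunnel survival, dominance logic, monotone
screening benefit, PSA/CEAC coherence — is correct, not that the
synthetic epidemiology matches any real population. Strategy rankings
under synthetic histories (e.g. which arm is optimal at a given
willingness-to-pay) are illustrative only; with the published outcome
table bundled in `inst/extdata/published_outcomes.csv`, the comparison
layer reproduces the published CUR/ICUR columns to rounding precision.

## Comparison layer

`efficient_frontier()` sorts by ascending cost, removes strongly
dominated strategies, then iteratively removes extended-dominated members
until neighbor ICURs increase strictly. Cost ties keep the higher-QALY
arm; exact ties in both dimensions keep the lexicographically smallest
code (determinism). The tests verify the frontier against an exhaustive
pairwise/convex-combination dominance search on seeded random outcome
sets. `net_monetary_benefit()` and `optimal_strategy()` implement the
willingness-to-pay view; `classify_icur()` applies the 1×/2×/3×
per-capita-GDP bands.

## Sensitivity analysis

One-way sweeps re-evaluate all strategies at a parameter's range
endpoints; the tornado ranks parameters by the spread of the base-case
optimum's NMB at λ = ¥70,653 (NMB rather than ICUR, because ICUR against
a moving comparator is discontinuous where the frontier recomposes).
`threshold_locate()` finds optimal-strategy switch values by coarse scan
plus bisection, returns the lowest switch and flags multiplicity when the
argmax changes more than once. The PSA samples all distributed parameters
jointly and independently (no published correlation structure exists);
transition probabilities are held fixed by default
(`options$psa_transitions = "uniform20"` perturbs them ±20% uniformly).
Iteration *i* uses child seed `seed + i`, so subsets are reproducible.
CEAC ties split equally, so probabilities sum to one exactly.

## Problem sizes and numerical tolerances

The test suite runs the full 41-arm grid on 20 seeded synthetic histories
for conservation (tolerance 1e-9 per cycle), a 200-iteration PSA over all
41 arms for the acceptability curves, 50 seeded outcome sets against the
brute-force frontier oracle, and 100,000 draws per distribution for
moment calibration (3 standard errors). The acceptance script uses a
100-iteration PSA over the seven reference arms. These sizes keep a full
run in the low minutes on one CPU while leaving Monte-Carlo error well
below the asserted tolerances; `run_psa(n = 1000)` reproduces the
published analysis's sampling effort directly.

## Known limitations

* The synthetic natural history is structurally faithful but not
  calibrated to registry data; absolute cases, deaths, costs and QALYs
  under synthetic inputs are not comparable to published absolute values.
* Specificity has no base-case economic consequence unless
  `options$fp_cost` is set, since false positives are resolved in-session.
* Compliance is memoryless across rounds; persistent attender/refuser
  subgroups would require cohort stratification.
* No correlation structure in the PSA, no EVPI, no budget-impact view.
* A single closed cohort entering at 40; no successive birth cohorts.
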