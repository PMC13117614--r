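---
title: "Model methods: decision tree, Markov cohort engine, calibration and uncertainty analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: decision tree, Markov cohort engine, calibration and uncertainty analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lcscea` implements a health-economic model of a single round of low-dose CT
(LDCT) lung cancer screening versus passive surveillance (voluntary periodic
check-ups with chest X-ray, no recall system) in a population aged 55–80
with former occupational asbestos exposure and at least 10 pack-years of
smoking. This vignette is the package's account of the model: its structure
and assumptions, the parameters that matter, the numerical choices, what the
synthetic defaults do and do not represent, and the known limitations.

## Model structure

The model couples a **decision tree** (the screening round and its immediate
consequences) to a **Markov cohort model** (lifetime follow-up in 3-month
cycles). The population is split into 12 strata — sex × six age groups
(55–59, …, 75–79, 80) — each entering at its band midpoint age (80 for the
open band) and simulated separately; results are aggregated with the stratum
weights.

**Decision tree.** In the screening arm, a stratum's screen-detectable
prevalence enters the *diagnosed* stage I–IV states according to the
screening-arm stage distribution; everyone else is cancer-free, and a
fraction of them (the age-band-specific LDCT false-positive probability)
incurs a one-off false-positive work-up cost and anxiety disutility before
returning to the no-cancer state. In the standard-care arm the *same*
prevalence mass enters the *undiagnosed* stage states with the *same* stage
distribution: false negatives at screening are deliberately not modelled,
which makes the two arms start with identical cancer mass stage by stage
and confines the intervention effect to earlier diagnosis (the stage
shift). Cancer-free standard-care participants attend a check-up within the
first year with probability 0.10 and can incur an X-ray false positive.

**Markov model.** States are: no lung cancer; undiagnosed stage I–IV
(standard care only — the screening arm's undiagnosed branch is removed by
construction); diagnosed stage I–IV with a *tunnel* on time since
diagnosis; death from lung cancer; death from other causes. The tunnel has
20 quarterly slots for years 1–5 since diagnosis plus one absorbing "year
6+" slot, so lung-cancer mortality can depend exactly on stage, year since
diagnosis (1–5), sex and age band (55–69 / 70–84), with a single constant
probability from year 6 onward. Diagnosed people remain in their diagnosis
stage until death; relapse and remission are not modelled as states (their
effect is embedded in the mortality probabilities). Undiagnosed people can
progress one stage per cycle (I→II→III→IV), be diagnosed, or die of other
causes; they cannot die of lung cancer before diagnosis.

**Event order within a cycle** is a model constant, applied identically in
the engine and in calibration: (1) other-cause death from all alive states,
(2) lung-cancer death from diagnosed states, (3) diagnosis of undiagnosed
states, (4) stage progression of the remaining undiagnosed I–III; tunnels
then advance one slot and the newly diagnosed enter year-1/slot-1. At this
cycle length the ordering visibly changes results (e.g. a person cannot be
diagnosed and die of lung cancer in the same cycle), which is why it is
fixed and documented rather than left implicit.

**Ageing.** Each stratum's age advances 0.25 years per cycle. All
age-banded inputs — other-cause mortality (single year of age), lung-cancer
mortality band (55–69/70–84; ages above 84 carry the 70–84 values forward),
utility band (55–64/65–74/75+) — are re-evaluated from the current cohort
age every cycle. Death is certain on arrival at age 100, which bounds the
lifetime horizon.

## Accounting

Life years, QALYs and costs are accumulated per cycle, **half-cycle
corrected** and **discounted at 3% per year**. The half-cycle correction is
trapezoidal: each cycle contributes the average of its start- and
end-of-cycle (utility-weighted) alive mass, discounted at the cycle
midpoint. With the correction disabled the accrual reduces to the plain
left Riemann sum (a regression guard in the tests). One-off quantities
cannot be half-cycle corrected: decision-tree costs and disutilities fall
at time zero undiscounted, and the stage-specific diagnosis-and-treatment
cost is charged once per person at the cycle in which the diagnosed state
is entered, discounted to that cycle (screen-detected baseline cases at
time zero).

Utilities: cancer-free (and undiagnosed, who are asymptomatic by
construction) people carry the sex/age-band no-cancer utility. Stage
utilities are the stage-I reference utility times published stage ratios,
scaled by the ratio of the current no-cancer utility to the table maximum —
so the age decline carries into the cancer states and a stage utility can
never exceed the no-cancer utility of the same sex and band. After the
fifth year since diagnosis the stage utility continues to apply (the
cure-after-year-5 scenario switches it to the no-cancer utility).

Detection costs: EUR 179 per screening participant (LDCT pathway including
operating and administrative costs) against EUR 14 per standard-care person
in year 1. The latter is *derived* as check-up attendance (0.10) × check-up
cost (EUR 140), so switching attendance off removes the cost, as it should.
After year 1 the arms share the routine surveillance costs, which
therefore cancel and are omitted; the standard-care arm keeps a detection
cost only for the newly diagnosed (one check-up, EUR 140, at the diagnosis
cycle — the source value is not published, so the implied check-up cost is
used; this is a package choice).

## Calibration of diagnosis probabilities

The 3-month diagnosis probabilities from undiagnosed stages I–III are not
observable inputs; they are chosen so that the standard-care arm's
distribution of stage *at diagnosis* reproduces the observed standard-care
stage distribution, given the fixed progression probabilities and the fixed
stage-IV diagnosis probability. `simulate_stage_at_diagnosis()` runs the
undiagnosed sub-chain to exhaustion (undiagnosed mass < 1e-10, bounded by
the age cap) and `calibrate_diagnosis_probs()` solves the three-parameter
inverse problem by damped fixed-point iteration on stage-share ratios,

p_s ← p_s · (target_s / simulated_s)^λ,  λ = 0.5, clipped to [1e-6, 1],

to a per-stage absolute tolerance of 1e-4 within 500 iterations, falling
back to Nelder–Mead on the log scale if the fixed point stalls.
Non-convergence is always flagged, never silent. Calibration pools the
strata with weights (stratum weight × prevalence) by default — the
alternative, per-stratum calibration, is exposed via `by_stratum = TRUE`
since mortality differs across strata and either reading is defensible.
The tests verify the sub-chain against a closed-form geometric series on a
two-stage toy and against absorbing-state linear algebra (`solve(I − Q)R`)
on time-homogeneous instances, and verify calibration by parameter-recovery
round trips on random parameter sets.

**Overdiagnosis** is computed from the same sub-chain as a cohort
counterfactual: the screen-detected cohort (screening-arm stage
distribution) is pushed through the standard-care undiagnosed chain with
the calibrated probabilities, and the mass dying of other causes before
diagnosis is the overdiagnosed fraction (reported per 10,000 screened).
This is deterministic and exactly consistent with the cohort engine, as
opposed to a paired microsimulation estimate.

## Synthetic default parameters

The study's stratum-level inputs (per-age prevalence, mortality tables,
utilities, unit costs and the PSA hyperparameters) are in appendix tables
that are not publicly deposited. The package therefore ships a **synthetic
default parameter set** (`default_paramset()`): values chosen once to be
epidemiologically plausible, constrained so that every published aggregate
is reproduced by construction:

* population-weighted screen-detectable prevalence **0.0253**, with an age
  profile rising from 55–59 to 75–79 and dipping at 80;
* population-weighted LDCT false-positive probability **0.180** (bands <65
  and ≥65 in a fixed 1.2 ratio, the older band higher);
* detection costs **EUR 179** (screening) and **EUR 14** (standard care,
  year 1); probability of surgery in a false positive **0.008**;
* 3% discounting, EUR 25,000 threshold, 2000 PSA iterations.

Everything else is a documented, plausible stand-in: stratum weights are
older-skewed and 70% male (the exposed workforce was predominantly male);
stage distributions use a screening distribution concentrated in stage I
that stochastically dominates the standard-care distribution; lung-cancer
mortality declines with years since diagnosis and rises with stage (5-year
survival roughly 70/45/25/5% across stages I–IV before sex/age
adjustment); other-cause mortality is a Gompertz-type curve adjusted upward
for asbestos exposure, male above female. The emitted YAML header labels
the file as synthetic. Consequently the package's *absolute* results (QALY
gains, credible intervals, the overdiagnosis count) are not expected to
equal the published ones — those depend on the unpublished tables — while
the printed aggregates above, the structural identities and all
directional/ordering results are reproduced. Passing tests demonstrate the
machinery is correct under realistic conditions, not that the synthetic
inputs equal the study's.

## Probabilistic sensitivity analysis

Parameter families follow convention for cost-effectiveness models: Beta
for probabilities and utilities (method of moments from the base-case mean
with coefficient of variation 0.2 by default), Gamma for costs (CV 0.2),
Dirichlet for the two stage distributions (concentration 100, drawn jointly
so they stay on the simplex), point mass for structural settings (discount
rate, cycle length, stratum weights, the age cap). Distinct parameters are
independent. Within a table-valued block that a single source pins down —
the lung-cancer mortality table (per stage), other-cause mortality (per
sex), the prevalence age profile, the no-cancer utility table — one
anchored Beta draw moves the whole block on the hazard scale
(`p' = 1 − (1 − p)^(draw/anchor)`), preserving the block's internal age,
year and band orderings while its level carries the uncertainty. Fully
independent per-cell draws would routinely invert those orderings (e.g.
stage I deadlier than stage IV), which no draw from the underlying sources
could produce.

Each of the 2000 iterations re-runs the full pipeline: draw, **recalibrate**
the diagnosis probabilities against the sampled standard-care stage
distribution (warm-started from the base-case solution; a fixed-calibration
fast mode exists), run both arms for all strata, aggregate. Iterations
whose calibration fails are excluded and counted, never silently dropped.
Summaries are means and central 95% credible intervals using R's type-7
linear-interpolation percentiles (so bounds are reproducible); ICERs are
ratios of means, matching how the subgroup-weighted ICERs are defined. The
CEAC reports, per threshold λ on a 0–60,000 EUR grid (step 1,000), the
fraction of iterations with λ·ΔQALY − ΔCost ≥ 0. Draws are deterministic
given `(seed, iteration)`, so runs are reproducible and individual
iterations can be reconstructed.

## Scenario analyses

Seven named scenarios transform the base parameter set declaratively
(`apply_scenario()`), each a pure function returning a valid set differing
only in its scenario fields: reduced overall prevalence (rescaling the age
profile to a lower weighted mean, 0.011); a less favourable screening stage
distribution; lower lung-cancer utilities; cure after year 5 (post-year-5
lung-cancer mortality zero and no-cancer utility); higher administrative
and operating costs (+EUR 16 per participant, reproducing the published
164→180 detection-cost shift); a reduced LDCT false-positive probability
(×0.73, calibrated to the published 66→48 false-positive cost component);
and alternative stage II–IV treatment costs as ratios to stage I. Scenario
replacement values are configuration with synthetic defaults; overrides are
accepted per scenario. Scenario PSAs reuse the base seed (common random
numbers) so between-scenario differences are not inflated by Monte-Carlo
noise; a resampling mode is available by passing different seeds.

## Numerical choices

* Annual→cycle probability conversion uses the constant-rate formula
  `1 − (1 − p)^(1/n)`; parameter files may declare `probability_scale:
  annual` and are converted on load.
* Sum-to-one and occupancy-conservation tolerances are 1e-9 absolute
  (double-precision construction noise); sub-chain exhaustion at 1e-10
  mass; engine extinction at 1e-12 alive mass, guarded by the age cap.
* Per-10,000 report values round half away from zero; internal values are
  never rounded. Report CSVs round costs to whole EUR and effects to four
  decimals, mirroring printed precision; curve data stay unrounded.
* The engine is vectorised across strata (state × stratum matrices per
  cycle; 91 states = 1 no-cancer + 4 undiagnosed + 4×21 tunnel slots + 2
  absorbing), which keeps a full 2000-iteration PSA with per-iteration
  recalibration to a few minutes on one CPU. Problem sizes used in the
  shipped tests — 100 random parameter sets for conservation, 50 for
  calibration recovery, one million individuals for the microsimulation
  cross-check — were chosen to give tight statistical power while keeping
  the default test run comfortably fast.

## Validation strategy

Beyond unit tests with hand-computed expectations, the suite checks:
occupancy conservation and absorbing-state monotonicity over random
parameter sets in both arms; exact agreement of the engine's one-cycle
update with a hand-derived transition; the closed-form life-year total
under zero mortality (100 − start age + half a cycle); agreement of the
cohort engine with an independent one-million-individual microsimulation
(same event order, per-person Bernoulli transitions, written separately
from the engine) within three standard errors on life years, QALYs and
lung-cancer deaths; calibration round trips; the decision-tree structural
identity (screen-diagnosed mass = standard-care undiagnosed mass, stage by
stage, for any valid parameter set); PSA point-mass collapse to the
deterministic result, bitwise reproducibility under a fixed seed, and CEAC
monotonicity whenever every iteration gains QALYs; and the published
directional orderings of the scenario analyses.

## Known limitations

* All defaults beyond the published aggregates are synthetic; absolute
  outputs are illustrative of the machinery, not estimates for the study
  population.
* No relapse/remission states; post-year-5 mortality is stage-, sex- and
  age-independent by design.
* False negatives at screening, incidental findings, repeated screening
  rounds, smoking-cessation co-interventions and a societal perspective
  are out of scope, as in the modelled analysis.
* Screening-anxiety disutility applies to all screened participants (the
  natural reading of "participation"); whether it should instead apply to
  all invited is unresolved and would only lower the screening arm's QALYs
  slightly.
* Surgeries in false positives are counted, not costed separately: their
  cost is taken to sit inside the bundled false-positive work-up cost.

## A worked call

```{r, eval = FALSE}
library(lcscea)
params <- calibrate_params(default_paramset())
fit <- run_cea(params, calibrate = FALSE)
glance(fit) # per-participant incremental results
psa <- run_psa(params, n_iter = 2000, seed = 1)
glance(psa)
autoplot(psa, "ce_plane")
autoplot(psa, "ceac")
run_scenarios(params, psa = FALSE) # deterministic scenario table
```
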