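---
title: "Two-stage multi-objective ICU bed allocation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multi-objective ICU bed allocation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icualloc)
library(dplyr)
```

## The planning problem

An intensive-care unit with `Q` interchangeable beds plans one horizon of
`T` days (7 in the defaults) for three patient populations:

* **current ICU patients**, already in beds, each with a remaining length of
  stay (LOS) counted from day 1;
* **elective patients**, each with an expected admission day `Exp_i`, a LOS,
  and a *loss of chance if postponed* — a severity weight of 0.1 (mild),
  0.5 (moderate) or 0.9 (severe) applied to every day of delay;
* **emergency patients**, arriving unscheduled with daily counts modelled as
  Poisson with per-day rate `lambda_t`, each drawing a LOS from a discrete
  distribution.

A patient admitted on day `t` with LOS `L` occupies a bed on days
`t .. t+L-1`; occupancy beyond the horizon is truncated in every objective.
Days are 1-based.

Because arbitrarily large arrival counts have vanishing probability, the
model caps day `t` at `Mp_t`, the smallest count whose cumulative Poisson
probability reaches a truncation quantile (0.999 by default; the quantity
"maximum plausible arrivals" is not otherwise a well-defined integer). The
realised daily count is drawn from the Poisson law conditioned on this cap.

## Stage 1: allocation under arrival uncertainty

A *schedule* fixes each elective's admission day (or leaves it out), carries
one realised emergency stream, and implies the per-day occupancy series
`Oc_t`. Three objectives are evaluated, each averaged over the horizon:

* `f11`, the **bed occupancy rate** `mean(Oc_t / Q)` — maximized; it can
  exceed 1 because emergency arrivals may overflow the stock (the hard
  capacity constraint `elective + current <= Q` binds only the schedulable
  populations);
* `f12`, the **delay index** — the mean over admitted electives of
  `loss * (admission day − expected day)` — minimized; electives are never
  admitted before their expected day, and a schedule admitting no electives
  scores 0 (it is dominated anyway);
* `f13`, the **emergency admission rate** `mean(em_t / Mp_t)` over days with
  a positive cap — maximized.

`run_stage1()` optimizes these with an elitist NSGA-II whose operators are
problem-specific:

* **individuals** are built current-patients-first, then an emergency stream
  is sampled, then electives are placed at random feasible days at or after
  their expected day — so every individual is feasible by construction. The
  emergency genes are sampled once per individual and never touched by the
  operators; the final front therefore mixes arrival scenarios, from
  emergency-light to emergency-heavy plans.
* **crossover** picks two electives and exchanges their admission days
  inside each parent; the exchange stands only if both children respect
  capacity and expected days over each patient's full stay.
* **mutation** deletes one elective admission and inserts an unadmitted
  elective of no longer LOS at a random feasible day.
* **re-insertion** fills any remaining vacancies: unadmitted electives are
  taken by priority (loss of chance descending, LOS ascending, id
  ascending) and placed at the earliest feasible day. Insertions only
  consume capacity, so one ordered pass is maximal.

Selection is binary tournament on (front, crowding); survivors are the best
`P` of parents plus offspring by rank then crowding; crossover applies per
offspring pair with probability `Cr`, mutation per individual with
probability `Mr`. Defaults (`P = 100`, `G = 200`, `Mr = 0.1`, `Cr = 0.7`)
follow the case-study settings. Tie-breaks are deterministic (ascending
patient id, then day), so a run is bit-reproducible for a fixed seed.

Because re-insertion runs after every operator batch, the search space is
the set of *maximal* feasible admission maps — plans that waste a fillable
bed-day are unrepresentable. The exact-front tests enumerate exactly that
space; over all feasible maps the zero-delay, low-occupancy corner of the
front is unreachable by design.

## Stage 2: re-allocation under LOS extensions

After stage 1 is frozen, stays may lengthen. A *disturbance draw* extends
every elective's LOS and every current patient's remaining stay by a value
from a discrete extension distribution, and adds a new emergency stream from
the same arrival model. Two extension modes exist: **additive** (the drawn
value is extra days; the case-study table `0:4` days with probabilities
0.40/0.25/0.20/0.10/0.05 is the default) and **multiplicative** (the drawn
value is a growth fraction `r` and the new LOS is the smallest integer at
least `LOS * (1 + r)`); the two formulations conflict in their source, so
both are kept and additive is the default. Extensions apply to elective and
current patients only. The combined emergency stream is truncated at
`Mp_t` — the cap is part of the disturbance, not a strategy decision — and
stage-1 arrivals keep their identities so plan similarity is well defined.

Two objectives compare a repaired schedule with the frozen reference:

* `f21`, **similarity**: the fraction of the reference plan's occupied
  (patient, day) pairs preserved. Beds are homogeneous, so matching is
  bed-agnostic by default and normalized by the reference plan's
  patient-days; `normalize = "max"` and `by_bed = TRUE` (matching on the
  deterministic first-fit bed labels) are provided because layout-level
  similarity reports from the motivating case study are consistent with a
  bed-sensitive, stage-2-normalized metric.
* `f22`, **added beds**: the largest daily excess of the repaired bed
  requirement over the reference requirement, where a day's requirement
  counts every patient served (emergency overflow included).

Three repair strategies are provided (`repair_strategies()` runs all):

* **elective-first** keeps every elective and current assignment and
  commits beds to the whole admissible emergency demand; arrivals landing
  on days whose occupancy already fills the stock are displaced onto added
  beds and reported as rejected. It preserves the elective plan exactly
  (`f21 = 1`) at the price of the largest bed addition.
* **emergency-first** serves all emergencies and current patients; each
  elective keeps its stage-1 day if the extended stays still fit (so a zero
  disturbance reproduces stage 1 exactly) and otherwise moves to the
  earliest feasible day by re-insertion priority; late or dropped electives
  are counted as postponed.
* **recall** re-runs the evolutionary search (`run_stage2()`) over
  (maximize `f21`, minimize `f22`) and returns the front member with the
  fewest added beds, ties to higher similarity.

The recall search must not degrade any stage-1 objective: candidates with
lower `f11`, higher `f12` or lower `f13` than the reference are handled by
constrained domination — any compliant candidate dominates every
non-compliant one, and non-compliant candidates rank by total violation.
This degenerates to plain rejection whenever compliant candidates exist,
but never leaves the population empty when a draw makes the bounds
momentarily unattainable; if no compliant solution is found the front is
returned flagged `feasible = FALSE` with a warning. The stage-2 population
is initialized fresh (not seeded from the reference plan), with the fixed
emergency stream: half the individuals place electives at random feasible
days and half at their earliest feasible day — the latter start on the
compliant side of the delay-index bound, which matters when the reference
delay is near zero. The stage-2 defaults are smaller (`P = 30`, `G = 40`)
because the hard bounds and the fixed emergency genes shrink the effective
search space. If the reference schedule itself still fits the stock under
the draw it is returned unchanged.

## Baselines and comparisons

`run_mosa()` and `run_mots()` share the encoding, the neighbourhood (the
mutation move, or an in-place exchange of two electives' days, followed by
re-insertion) and the objectives, and maintain an external archive of
non-dominated solutions (capacity 100, crowding-pruned):

* **MOSA** cools geometrically (1000 to 1e-3 at rate 0.95 — 270 levels, one
  move per level by default). A non-worsening neighbour is always accepted;
  a worsening one with probability `exp(-delta / T)` where `delta` is the
  equal-weight sum of min-max-normalized objective worsenings (there is no
  canonical acceptance energy for multi-objective annealing; this is the
  package's choice, configurable through the parameter object).
* **MOTS** generates 10 candidates per iteration for 200 iterations; the
  best non-tabu candidate by (rank, crowding) becomes current; tabu
  attributes are the changed (elective, old day, new day) triples, held for
  a tenure of 5 in a list capped at 50; a tabu candidate that enters the
  archive is admissible (aspiration). Attributes rather than whole
  solutions are stored because the stochastic emergency genes make solution
  hashing brittle.

`compare_algorithms()` runs all three per seed (each algorithm freezes its
own compromise reference, all share one extension draw) and applies a
one-sided paired t-test of "the evolutionary search's metric mean is
smaller"; the default metric is the achieved added beds — the stage-2 headline
quantity — and it is exposed as an argument.

`scenario_sweep()` applies the five case-study extension scenarios S1–S5
(S1 equals the base table; later columns shift mass toward longer
extensions and stochastically dominate earlier ones) to one stage-1 front
per seed. Scenario draws use common random numbers: extensions are
inverse-CDF samples over the sorted support and every scenario within a run
shares the disturbance substream, so a dominating scenario draws
pointwise-larger extensions and the scenario effect is not confounded with
sampling noise. Heavier extension load then only adds patient-days, and the
mean added beds are nondecreasing from S1 to S5.

## The synthetic generator

No usable patient-level dataset accompanies the source material, so
`generate_instance()` draws instances with the case study's structure:
24 beds, a 7-day horizon, 100 elective requests, 3 current patients,
expected days uniform over the horizon, elective and current LOS uniform on
1–7 days, the three loss-of-chance levels equally weighted, emergency LOS
uniform on 1–5 days (the values the case-study data exhibit), and
daily arrival rates uniform on 3–6 per day — a rate of 4.5/day reproduces
the case study's day-one admission cap of 12 at the 0.999 truncation
quantile, and weekly emergency admissions then land in its 30–55 range.
Each purpose (instance structure, arrivals, extensions, search) draws from
its own derived seed, so stage-2 disturbances are reproducible
independently of search randomness.

What the generator does *not* emulate: weekday/weekend arrival seasonality,
correlation between severity and LOS, heavy-tailed stays, or readmissions.
Tests passing on these instances show that the algorithms and accounting
behave as specified under the stated statistical structure, not that the
method's case-study numbers transfer to any particular hospital.

## Numerical choices and problem sizes

* Feasibility tolerances on the stage-2 bounds are `1e-9` (the objectives
  are short rational sums; the tolerance only absorbs float noise).
* Probability vectors must sum to 1 within `1e-9`.
* Duplicate genotypes are removed from reported fronts; duplicates may
  coexist inside the population, as in the standard algorithm.
* Degenerate inputs: a zero arrival rate gives an empty stream and a point
  occupancy distribution; an instance with no electives yields the single
  trivial solution; an all-mass-at-zero extension table is a no-op draw.
* The test suite runs the full search at the default parameters only on
  enumerable toys (4 electives); property checks on full-size instances
  use reduced budgets (population 16–50, 10–100 generations), and the
  qualitative case-study patterns are checked across 20 generated
  instances at population 50 / 100 generations with the stage-2 search at
  30 / 40 — sizes chosen to exercise convergence without waste.
* Exact hypervolume (2-D staircase sweep, 3-D slicing) ranks repeated runs;
  it is not used inside any search loop.

## Known limitations

* The emergency admission cap couples the `f13` denominator to the
  truncation quantile; changing the quantile rescales `f13` values between
  configurations.
* Under the default similarity metric an elective-first repair always
  scores exactly 1; layout-level (bed-identity) similarity is available but
  not default.
* Stage-2 MOSA/MOTS start from a repaired reference schedule (a trajectory
  method needs a compliant starting point under the hard bounds), so their
  stage-2 archives are biased toward the reference in a way the
  population-based recall search is not.
* All beds are interchangeable: ward layout, staffing and equipment
  constraints are out of scope, as is any rolling-horizon re-optimization
  beyond the single repair step.
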