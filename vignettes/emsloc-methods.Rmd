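---
title: "Methods: models, simulator and design choices in emsloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator and design choices in emsloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsloc)
```

`emsloc` supports the strategic question of *where ambulance stations
should stand* in a large region that mixes dense towns with sparse
countryside, for a two-tier fleet of ALS (physician) and BLS (paramedic)
units. This vignette documents the science inside the package: the
demand and travel models, the three location models and how they are
solved, the discrete-event simulator, the busy-fraction feedback loop,
and every place where the design was genuinely open and a choice had to
be made.

## Demand model

Demand zones are municipalities. The annual patient count of
municipality $j$ is
$$b_j = \sum_{k} rate_k \, pop_{kj} / 1000,$$
with age groups $k \in \{0\text{–}14, 15\text{–}64, 65+\}$ and default
incident rates of **26.09, 69.12 and 267.07** cases per 1,000 persons
per year — elderly people call EMS an order of magnitude more often than
children, which is why the age structure (and the aging index, the
65+/under-65 ratio) matters for station placement. Rates of this form
arise from allocating a national dispatch total $D$ over age groups
proportionally to a patient sample:
$rate_k = 1000\, D\, n_k / (pop_k\, n_{total})$
(`compute_incident_rates()`).

High-priority (First Hour Quintet: chest pain, severe trauma, stroke,
severe respiratory difficulty, cardiac arrest, unconsciousness) demand
$b^{FHQ}_j$ uses a per-age-group FHQ share. Only the aggregate share —
**26.51%** of all patients — is available, so the default is that
constant across age groups; the vector is configurable because the true
share very likely rises with age. Demand is linear in population, so
merging municipalities adds their demands exactly; this is tested.

## Travel model

Travel times are deterministic shortest paths on the road network, with
per-edge times $60 \cdot \text{km} / v$ where the speed $v$ depends on
road category (motorway … minor road), urban vs. rural setting, driving
mode (*lights and sirens* for response trips vs. *standard* for the
journey home) and time-of-day regime (off-peak, morning rush 06:30–09:00,
evening rush 15:00–18:00). The speed table is derived from ambulance GPS
records; urban lights-and-sirens motorway speed is 100 km/h off-peak,
rural 110 km/h. Two urban rows of the source table (residential and
minor roads) are typographically corrupted; they default to conservative
values below the local-road row, are configurable through
`speed_model()`, and are excluded from acceptance examples. Lights-and-
sirens speeds dominate standard speeds everywhere, so response-time
matrices dominate return-time matrices elementwise (tested).

The optimization stage uses the lights-and-sirens, off-peak matrix:
response trips are driven at maximum speed, and the models need one
matrix, not a schedule. A trip keeps the regime it started in — trips are
short (minutes) relative to the rush windows (hours).

A demand point is *covered* if a station is within
$T^{max} = 7$ minutes: the widely used 8-minute standard for critical
patients minus one minute of pre-trip (activation) delay. Coverage uses
the closed inequality $t_{ij} \le T^{max}$ and neighbourhoods are nested
in $T^{max}$ (tested).

## Location models

All models site $p$ stations, where $p$ is the current station count —
the premise is relocation, not expansion. Preprocessing first decides
which stations cannot move:

* towns with $b_j > capacity \times$ (stations there) are *fully
  engaged*: their stations are fixed, and the demand they absorb
  ($capacity$ per ambulance, default 3,000 calls/year) is removed;
* multi-station towns with $b_j < capacity$ keep one fixed station *with
  spare capacity* (set $I_1$) that may also serve neighbours; the rest
  are freed;
* everything else is relocatable.

Only $b_j$ is reduced, not $b^{FHQ}_j$: the source for this rule speaks
of demand volume only, and fully-engaged towns retain their stations in
their own neighbourhood, so FHQ coverage there is unaffected.

**MEXCLP.** Expected coverage discounts the $k$-th station in a
neighbourhood by the probability $q_j^{k-1}$ that the first $k-1$ are
busy: the objective is
$\sum_j b^{FHQ}_j (1 - q_j^{m_j})$ once the station count $m_j$ per
neighbourhood is fixed. **Weighted p-median**: minimize
$g = \sum_{ij} t_{ij} b_j z_{ij}$ with every demand point assigned to
its nearest open (or spare-capacity) station. **Bi-criteria**: solve
MEXCLP first, then the p-median constrained to coverage
$f \ge f^\ast (1 - 10^{-6})$ — the relative tolerance absorbs
floating-point slack that an exact floor would turn into spurious
infeasibility. **Hierarchical pq-median**: p-median lower level; the
upper level picks $r$ of the opened/fixed sites for ALS units minimizing
the ALS analogue $g_{ALS}$, which can never beat $g$ because ALS sites
are a subset of all sites.

### How the MILPs are solved

Once the open-site vector $x$ is fixed, every other variable of these
models is determined in closed form: the coverage variables $y_{jk}$
follow from $m_j$ (their objective coefficients strictly decrease in
$k$, so the LP optimum is integral), and the assignment variables
$z_{ij}$, $v_{ij}$ go to the nearest assignable site. The models are
therefore *subset-selection* problems, and the package solves them
exactly with a depth-first branch-and-bound over site subsets:

* coverage: upper bound = current $f$ plus the largest remaining
  single-site marginal gains (valid by submodularity);
* median: lower bound = $\sum_j b_j \min(d_j^{chosen}, d_j^{suffix})$,
  where the suffix minimum over not-yet-considered candidates is
  precomputed (candidates are scanned in index order, so the remainder
  is always a suffix);
* ties are broken toward the lexicographically smallest site set by
  exploring the include-branch first and accepting strict improvements
  only — determinism is tested by replay.

This replaces the commercial MILP solver used in comparable studies; no
LP/MILP engine is required at run time. Correctness is established
against brute-force enumeration (`utils::combn`) on 50+ seeded instances
with $|I| \le 10$, $p \le 4$, for every model, with and without the
coverage floor.

### Kernel search

For instances beyond enumeration the package ships a kernel-search
matheuristic for the p-median stage: solve an exact restricted problem
over a *kernel* of promising sites, then repeatedly re-solve over kernel
∪ one *bucket* of outside sites, promoting into the kernel any site that
enters an improved incumbent; stop after a full pass without improvement
or `max_passes`. Classic kernel search seeds the kernel from the LP
relaxation and orders variables by reduced cost. Without an LP engine the
package seeds it combinatorially: a greedy p-median construction plus a
demand-weighted attractiveness score (the single-site improvement each
candidate would bring over the greedy layout). This preserves the
method's contract — monotone improvement over the initial kernel-only
solve, exactness when the kernel holds all variables, and agreement with
the exact optimum on all small test instances — which is what the test
suite pins down. Default sizes: kernel $\max(p_{new}+2,\,2p_{new})$,
bucket $2\times$ kernel.

### A-posteriori ALS allocation

The bi-criteria and p-median models are type-blind, so ambulance types
are assigned afterwards: fixed and unmoved stations keep their types;
displaced ALS units are matched greedily (closest pair first) to the
nearest still-untyped new stations; everything else becomes BLS; and the
ALS count is then forced to exactly $r$ (demoting the worst greedy
matches or promoting the BLS stations closest to a former ALS site, by
index — deterministic). The hierarchical model makes this step
unnecessary, which is precisely its argument.

## The simulator

A discrete-event, agent-based model of the full service pathway, one
ambulance per station:

* **Arrivals**: non-homogeneous Poisson process by thinning, with a
  piecewise-constant daily profile. The profile's peaks are at
  09:00–11:00 and 17:00–21:00; the magnitudes (1.5× and 1.4× the base
  rate) are a design choice — the peak *windows* are established, their
  heights are not published — and the profile is rescaled to the
  configured daily volume. Calls land in an ambient-population grid cell
  proportionally to its population, at the cell's road node.
* **Dispatch**: the closest available unit by travel time from its
  *current position* is sent regardless of type; if the call is FHQ and
  that unit is BLS, the closest available ALS is sent concurrently
  (`dispatch_rule()`). Returning units are available and get redirected
  from their interpolated position via the next node on their path; they
  skip the 1-minute pre-trip delay (their crew is already active),
  idle units incur it. If no unit is free the call queues — FHQ first,
  FIFO within class — and the queue is retried at every release.
* **Service**: lights-and-sirens travel (regime fixed at trip start);
  lognormal on-scene time by (priority, crew), CV 0.4 by default and
  degenerate at CV 0 for hand-traceable tests; Bernoulli transport with
  probability **0.77** for paramedic-only crews and **0.51** when a
  physician attends; transport to the nearest diagnosis-compatible
  hospital (fallback: nearest general); Erlang drop-off with
  per-hospital mean in the observed 7.1–36.2 min range; return home at
  standard speeds.
* **Dual dispatch**: the ALS unit is never cancelled, and a physician is
  deemed present (for the transport decision) whenever an ALS unit is
  assigned. A unit arriving after the scene has wrapped up is released
  on arrival. The alternative — cancelling the second unit — is not
  documented in practice descriptions, and never-cancel is the
  conservative choice for workload.
* **Workload**: busy = committed-to-patient time (en route, on scene,
  transporting, at hospital); returning counts as available time. This
  makes "workload" mean *unavailability for the next patient*, which is
  what the busy fraction $q_j$ of the MEXCLP needs. Replication = 91
  days by default, no warm-up deletion (transients of minutes against a
  13-week horizon), 10 replications with derived seeds, Student-t 95%
  intervals across replication means. Percentages use the population
  standard deviation for the workload CV.

Busy fractions for the optimizer: a candidate hosting ambulances gets
their mean workload; a candidate without gets the mean workload of
stations within 30 minutes; with none, the global mean (a defined
fallback for pathological geographies). Values are clamped below 1.

## The optimize–simulate loop

Busy fractions depend on the layout, which depends on the busy
fractions, so the loop starts from the incumbent layout, alternates
optimization and simulation, and stops when two *successive optimizer
outputs* have multiset overlap $\ge$ 1.0 (configurable down to ~0.98 to
mirror an "almost identical" criterion). Measuring convergence between
optimizer outputs — rather than against the incumbent — makes a frozen
busy-fraction vector a provable fixed point reached in exactly two
iterations, which the acceptance suite asserts. Ambulance types are
re-assigned inside every iteration, because the simulator needs a typed
fleet. `compare_models()` evaluates all layouts with identical master
seeds (common random numbers), so indicator differences are attributable
to the layouts.

## The synthetic region generator

Real inputs of this problem class — census age pyramids, open
road-network graphs, ambient-population rasters, operator trip logs — cannot
ship with a package. `generate_region()` emulates their statistical
shape from a seed: a connected road network (perturbed lattice by
default — connectivity by construction; a k-nearest-neighbour geometric
variant with explicit component stitching as an alternative),
log-uniform town sizes (400–4,000 rural, 5,000–60,000 urban), age-group
shares drawn from configurable ranges, a Dirichlet split of each town's
population over grid cells (ambient-population-raster heterogeneity with
one knob),
stations concentrated in the largest towns with ALS preferentially at
hospital towns (about a third of units are ALS), and hospitals with
Erlang drop-off parameters in the observed range.

What a green test on synthetic regions establishes: the algorithms are
correct (oracle equivalence), deterministic, and internally consistent
(conservation, invariants, parameter recovery). What it does not
establish: that any specific real region's headline indicators are
reproduced — those depend on real geography and proprietary trip data
and are explicitly out of scope; the acceptance suite therefore checks
desk-scale quantities and structural properties, not real-world tables.

## Survival impact

For the most critical patients, survival falls logistically with the
response time $t$ in minutes:
$$s(t) = \frac{1}{1 + \exp(-2.04492 + 0.045427\,t)}.$$
The unit of $t$ is a deliberate interpretation: with minutes, a
56-second reduction from an 11.37-minute baseline yields a gain of
0.61 percentage points, exactly the conventionally printed value;
seconds would not reproduce it. `expected_additional_survivors()` is the
plain product $n \cdot \Delta s$; applied to 26,003 annual critical
patients it gives ≈ 159, and the package deliberately does not hard-code
any alternative figure.

```{r survival}
survival_gain(11.37, 56)
expected_additional_survivors(26003, 11.37, 56)
```

## Numerical choices and limitations

* Objective comparisons use absolute $10^{-9}$ slack; the coverage floor
  a relative $10^{-6}$.
* `0^0 = 1` in R makes the coverage closed form correct at $q_j = 0$
  (uncovered points contribute 0, covered points their full demand).
* Travel matrices treat the network as undirected; one-way streets,
  turn penalties and stochastic travel times are out of scope.
* The p-median family opens at most one *new* station per site; fixed
  stations may stack (multi-station towns enter via preprocessing).
* Investment/relocation costs are not modelled; the $p$ and $r$
  parameters are the only levers for limiting change.
* Crew scheduling, triage modelling and hospital capacity are out of
  scope; secondary (inter-hospital) transports exist in the simulator
  but default to rate 0 because no rate is published.
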