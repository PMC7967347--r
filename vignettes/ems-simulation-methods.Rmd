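---
title: "Methods: rule-based discrete-event simulation of EMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based discrete-event simulation of EMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `emsdes`, the assumptions it
makes, the parameters that matter, and the choices taken where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The incident model

An *event* is one real-world emergency; it triggers one or more
*incidents*, each the mission of one EMS unit. Every incident carries a
timestamp chain along the canonical event sequence:

    call to dispatch → call to EMS unit → depart base → arrive scene
    → depart scene → arrive hospital → free → arrive base

Present fields must be non-decreasing in this order; `validate_scenario()`
enforces that plus coordinate ranges, closed priority/unit-type
enumerations, identifier uniqueness, referential integrity, the event
partition and roster validity. Violations are returned as data (entity,
field, rule), never raised, so ingestion pipelines can report them.

Internally all times are numeric seconds since a scenario epoch (an
ISO-8601 instant, by default a Monday so weekday masks anchor cleanly);
files carry ISO-8601 UTC strings. Seconds represent both the 15-minute
roster grid and sub-minute travel times exactly.

The **response time** of an event is the first arrival at the scene minus
the first call, both minima taken over the event's incidents. Three
start-point variants exist in practice and are explicit everywhere:
`TRANSIT_ONLY` (depart base), `PREP_PLUS_TRANSIT` (call to the EMS unit;
the Swiss convention and our default), and `FROM_DISPATCH_CALL`. The
**RTCR** is the share of events with RT ≤ MART; compliance uses `≤`
because "within 15 minutes" does not specify the boundary, and the
boundary case is asserted in the tests. RTCR is reported rounded to one
decimal; all comparisons (notably reserve-capacity gains) use the
unrounded value.

## Dispatching and the queue

High-priority incidents (default `{P1, P2}`; `S1` — a relocation with
suspected impairment — is *not* high priority by default but the set is
configurable) are served closest-idle: among units that are type
compatible, on shift, free, inside the optional distance/ETA cut-offs and
(optionally) in the incident's region, take the one with the smallest
ETA; ties go to the lexicographically smallest unit id so runs are
reproducible. Low-priority incidents take their historic unit if it is
among the candidates, else the closest idle one.

For incidents requiring a prehospital emergency physician while a
multicopter is in the fleet, the MCO flies iff (a) one is available, (b)
the round trip base → scene → base fits its range, and (c) its ETA beats
the ground physician car (or there is none). MCOs cannot carry patients,
so a transport incident served by an MCO additionally occupies the
closest ambulance as companion.

Unserved incidents wait in a two-class priority queue — high before low,
FIFO within class. Decision epochs are the incident call times; the queue
is re-evaluated whenever any unit becomes free or comes on shift (the
loop in the underlying flow chart does not specify re-evaluation
triggers; these are the only instants at which the candidate set can
change, so nothing is missed). An incident whose required type can never
be served (no compatible unit with any staffed interval, or all bases
beyond a cut-off) is marked UNSERVED; by default it counts as
non-compliant rather than leaving the denominator, which is the
conservative reading.

A shift ending during a mission never aborts it: the unit completes the
mission and the busy time outside staffed intervals is reported as
overtime (hours per year, annualized over the horizon).

## Travel times and service times

Travel time uses effective speeds per (unit type, priority):
`distance · detour / speed + overhead`, with great-circle distance on a
6371-km sphere, a ground detour factor (default 1.3), and a fixed
takeoff/landing overhead for air units. Default ground speeds are 62 km/h
for ambulances and 70 km/h for physician cars at P1, with non-privileged
priorities at 0.85 of that; operational speed profiles fitted to real EMS
traces are proprietary, so these are configuration values recorded with
every KPI set, not constants. An external routing backend (e.g. an OSRM
table service) can be plugged in as a function returning minutes; its
durations are scaled by a priority-specific factor modelling traffic
privileges. Road-class regression of speed parameters is out of scope.

Turnout, on-scene, handover and (when no hospital table is present)
transport durations are lognormal with configurable medians and log-scale
sigmas — distance-independent parameters of this kind are conventionally
taken from published studies, and ours are declared assumptions (defaults:
medians 2 / 15 / 15 / 12 min, sigmas 0.35–0.4). A `replay` switch reuses
each incident's historical durations instead, which is what makes the
*simulated historical* scenario comparable to history.

All draws are made **up front, indexed by incident**, from the config
seed. Consequently (i) runs are bit-for-bit deterministic given
(scenario, config, seed), and (ii) the STANDARD and UNLIMITED runs of one
scenario share draws, which turns the per-incident dominance of the
unlimited-resources bound into an arithmetic fact rather than a
statistical tendency: the unlimited run dispatches at the call instant
from the travel-time-minimal base, so no standard-mode assignment can
arrive earlier.

Hospital selection takes the nearest hospital (by travel time from the
scene) whose capability set contains the incident's tracer diagnosis —
the next neurosurgical or pediatric centre may be much further than the
next hospital. If no capable hospital exists within the cut-off, the
nearest general hospital is used and flagged `downgraded`. The record
format carries the diagnosis as an optional column (absent means
general), since capability gating is otherwise impossible.

In the default follow-up mode every mission departs from the unit's base
(`START_AT_BASE`), a deliberate simplification; `CHAINED` mode lets a
freed unit be dispatched from the location where it became free while on
its return leg. The returning unit is treated as located at its freeing
point for the whole return trip rather than interpolated along it — a
known simplification that biases chained ETAs slightly optimistic.

## The validation ladder and planning tools

Analysis proceeds historical → simulated historical → unlimited
resources. The unlimited bound caps what roster changes at fixed bases
can achieve; a bound below target diagnoses base locations, not fleet
size.

Reserve capacity: starting from S0 (the simulated historical scenario),
each iteration simulates every candidate — one 12-h day (07:00–19:00) or
night (19:00–07:00) shift at each base (the 12-h granularity is given;
the clock anchors are our choice) — and permanently adds the argmax-RTCR
candidate, ties to the smallest base id with day before night. It stops
at the target, when the best gain is below ε (default 1 pp — smaller
gains do not justify a staffed shift), or at `max_iter` (default 20,
bounding the |bases| × 2 × iterations simulation budget). One scenario
per step is retained, and the tests re-simulate each to its recorded
RTCR. Candidate units are ambulances unless configured otherwise.

The multicopter operation radius is
`min(speed · (t_max − overhead)/60, range / (2 · missions))`: the
time-limited radius at 72 km/h and 20 min is 24 km; at 80 km/h with a
50-km range the range limit binds at 25 km. The `missions_per_sortie`
parameter encodes an endurance reading under which a 150-km range
supports a 25-km radius over three missions without recharging; this is
one plausible interpretation, stated as such. Base siting uses greedy set
cover (repeatedly take the candidate covering the most uncovered demand
points; ties to the smallest index), checked in the tests against
exhaustive enumeration on instances with ≤ 12 candidate sites — the ILP
formulations of the location-allocation literature are out of scope.

## The synthetic generator

Dispatch-centre data are confidential, so experiments run on synthetic
scenarios that emulate the *statistical shape* of real ones: a
non-homogeneous Poisson arrival process with quarter-hour
piecewise-constant intensity (low overnight, rising after 06:00, a broad
daytime plateau, evening decline — digitized qualitatively, shipped as
data); an urban-cluster + rural-background spatial mixture; a priority
mix (defaults P1 .25, P2 .35, P3 .10, S1 .05, S2 .10, S3 .15 — invented
placeholders, recorded with every experiment); 70 % hospital transports
among primary incidents and all secondary ones; and day/night rosters.
Generated histories are completed by one engine pass (rounded to the
1-second resolution of real dispatch logs) so chains, historic unit
references and hospital assignments are internally consistent.

Default study conditions were fixed once, before any acceptance
measurement, at values a practitioner would call realistic: a ~30-km
study area, 4 bases, 2 ambulances per base per 12-h shift, 20,000
incidents per year. They yield RTCR ≈ 80–90 %, fleet utilization ≈ 25 %
and an unlimited bound above the 90 % target, matching the regime in
which operational systems sit.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: road-network travel asymmetries,
seasonal and weekday demand structure beyond a single weekend scale,
spatially varying priority mixes, inter-organization load sharing across
borders, and discontinued incidents. Conclusions about any real region
require that region's data.

Defect injection mutates exactly the requested number of records per
cleaning class (swapped timestamps; blanked scene arrival; blanked
hospital arrival of a transport) with disjoint targets, and returns the
manifest, which is the oracle for the cleaning tests. Cleaning applies
rules in the order inconsistent → missing-RT → incomplete-post-arrival
with single attribution, so the report is additive; "inconsistent" is
operationalized as an ordering violation among present fields (equivalently
a negative implied duration) or a call outside the horizon — the minimal
checkable reading of a rule that is stated but not defined. Records
flagged discontinued are removed beforehand and counted separately.
Fallback event grouping (for records without an event id) chains
incidents within 100 m and 5 minutes — conservative, configurable
thresholds.

## Numerical conventions and test problem sizes

Point-in-polygon counts the boundary as inside (implemented in-package by
ray casting with an explicit on-segment test; no installed geometry
package exposes this convention on plain lon/lat rings). Isochrone bands
are half-open with inclusive upper bounds, and travel minutes are rounded
at 10⁻⁹ before banding so a point exactly on a threshold lands in the
lower band regardless of float noise. Distances use the haversine formula
at the 6371.0-km mean radius via `geosphere`.

The dispatch-policy equivalence suite re-derives every assignment with an
independently coded brute-force oracle on 50 random scenarios of ≤ 8
units and ≤ 60 incidents with zero-dispersion service times (so the
oracle can reconstruct busy intervals in closed form); the upper-bound,
trade-off and recovery suites use 3–7-day scenarios at the default
annual volume, 20 seeds for the utilization trade-off, and one 365-day
scenario (~20,000 events) for demand-profile recovery. These sizes were
chosen as the smallest at which the respective properties are sharp.

## Known limitations

No dynamic relocation between bases (a reserved state exists for future
use); no multi-national queue-ranking policies; no imputation of missing
timestamps (records are removed, never repaired); a scalar effective
speed per (type, priority) instead of per-road-class speeds; community
assignment by polygon or nearest centroid only. The optimality gap of
greedy covering relative to an exact ILP is unbounded in theory (H(n)
factor) though it matched the exhaustive optimum's feasibility on every
tested instance.
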