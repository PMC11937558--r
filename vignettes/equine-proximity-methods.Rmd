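---
title: "Methods: proximity-sensor analysis of equine social spacing"
author: "equiprox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-sensor analysis of equine social spacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiprox)
```

## Scope

`equiprox` analyses 1 Hz dyadic distance streams from ultra-wideband (UWB)
proximity sensors worn by group-housed horses. From raw directed channels it
derives: cleaned per-dyad distance series; absolute and relative
interindividual distance statistics; time spent in proximity bins and each
horse's closest / least frequent associate; median-threshold social networks
with degree, betweenness and closeness centrality; and rule-based agonistic
approach/retreat events with per-horse-hour rates. A herd simulator with
known ground truth makes every stage testable without access to raw tracking
data.

## Cleaning model

UWB ranging errors arise from obstruction and poor sensor connection. Four
rules are applied per directed channel, in this order:

1. **Range**: samples above the maximum theoretical distance (taken as the
   enclosure diagonal, `100 * sqrt(L^2 + W^2)` cm) or below 5 cm (impossible
   given head-mounted sensor placement) are removed.
2. **Frozen runs**: any maximal run of bit-identical values longer than 10 s
   is removed in full. Genuine UWB measurements are inherently variable, so
   constancy indicates a stuck reading. The rule is strict — a run of
   exactly 10 identical samples survives — and the identity tolerance is
   zero centimetres.
3. **Feeder proximity**: samples where *both* animals are within 3 m of the
   hay feeder are removed (forced, not social, proximity); samples with only
   one animal near the feeder are retained. Feeder distances are looked up
   on each animal's feeder channel at the nearest reading within ±1 s.
4. **Replicate averaging**: the two directed channels (A→B, B→A) are
   technical replicates and are averaged per timestamp after filtering;
   timestamps present in only one channel are retained as-is.

Design choices the data source leaves open, decided here once: filters run
on the raw directed channels *before* replicate averaging (freezing is a
per-sensor-pair failure); duplicate timestamps within a channel are
collapsed by their mean before any filter; gaps are left as gaps (no
interpolation, no clock-drift correction). All removals are counted per
dyad and reported, and raw counts always equal kept plus removed.

## Distance metrics

The per-dyad statistic is the sample median of retained distances; its 95%
confidence interval is a seeded percentile bootstrap (1000 resamples), since
the source tables state a CI but not a method; an exact binomial
order-statistic interval is used as a test oracle for its width. The
*relative* interindividual distance divides the median (cm) by the space
available per horse (enclosure area / number of horses, m²), giving cm/m²:
low absolute + high relative distance signals forced proximity, low + low
signals voluntary proximity.

Group-level values pool **one value per dyad** (the dyad median), not raw
samples, so dyads with more retained samples do not dominate. For the pooled
relative distance two pathways exist — the median of per-dyad relative
distances (default) and the pooled median divided by space per horse — and
published group tables are not consistent with a single pathway, so the
output flags which one was used and the package never silently reconciles
them. Rounding is half-up to two decimals and happens only at the reporting
layer.

## Associations

Time-in-bin fractions divide the retained sample count per bin by the dyad's
total retained samples (1 Hz, one sample = one second). Bins are `<= 3 m`
(closed at 300 cm), `(3, 6]`, `(6, 9]`, `(9, 12]` m, plus an explicit
`> 12 m` remainder so the fractions always sum to one. The closest
(least frequent) associate of a focal horse is the partner with the largest
(smallest) `<= 3 m` fraction; ties break by smaller median distance, then
lexicographic id, and the relation is deliberately not symmetrised.
Associates are identified per condition (paddock and field separately).

## Networks

The mean distance per dyad, aggregated over the whole observation period,
fills a symmetric matrix. The binarisation threshold is the median of the
upper-triangle entries (each dyad once); an edge requires a mean distance
*strictly below* the threshold, so ties at the median produce no edge and an
all-equal matrix yields an empty graph. Centrality conventions are chosen to
be consistent with published per-horse tables: degree is the raw tie count;
betweenness is unnormalized with each unordered pair counted once and
fractional credit split among all shortest paths; closeness is the
unnormalized reciprocal of summed shortest-path lengths to the *reachable*
nodes (a hub adjacent to all five others of its component scores 1/5 = 0.2),
and an isolated node scores zero on all three. The implementation is a
Brandes-style BFS accumulation, tested exhaustively against an independent
matrix-power path-counting oracle on every graph with up to six nodes.
Graphs are exported as GraphML plus an edge-list CSV, with mean distances as
edge attributes; layout/visual styling is out of scope.

## Agonistic events

Speeds are finite differences, `(d[n] - d[n-1]) / (t[n] - t[n-1])`, so a gap
widens the denominator rather than inflating the speed. Steps beyond
800 cm/s are physically impossible for the animals and enclosures modelled
and are flagged as measurement errors; the later sample of a flagged step is
excluded from all event logic.

An **agonistic approach** is a window satisfying, jointly: a decrease of at
least 100 cm to a final distance below 200 cm within 3 s; a minimum closing
speed of 85 cm/s; involvement of exactly two animals; and consistent
direction of movement. Operationalisations, since only scalar dyadic
distances exist:

* Windows span up to 3 s of *contiguous* 1 Hz samples (up to 4 samples /
  3 intervals); an event never spans a cleaning gap or a flagged sample.
* The 85 cm/s floor applies to the window-mean closing speed
  (displacement/duration) by default; per-step jitter at 1 Hz makes
  instantaneous floors brittle. A per-step variant is available behind a
  switch (`speed_rule = "step"`).
* "Consistent direction" means monotone distance change within a 1 cm
  jitter tolerance.
* Overlapping qualifying windows of one dyad merge into a single event
  (earliest start, latest end); "two animals only" is enforced
  conservatively — concurrent events sharing an animal void each other.

A **retreat** is a rise of at least 100 cm within 3 s whose window starts
within 3 s of a detected approach's end; at most one retreat links per
approach. At the earliest qualifying start, the fastest (then longest)
window is taken, so a fast flight is classified by its fast leg rather than
diluted by a slow tail; the class is `high_retreat` when the window-mean
speed meets the 85 cm/s floor, `low_retreat` otherwise, and a high-speed
retreat is never double-counted as low. Rates are
`events / (horses x hours)`; with `horses = 1` this is the pooled
group-hour rate.

## Inference utilities

The Fisher–Pitman permutation test compares group means under
exchangeability with Monte-Carlo sampling (default 1000 iterations) and an
add-one correction, `p = (1 + #{|perm| >= |obs|}) / (1 + n_iter)`, so a
Monte-Carlo p-value is never zero; it is two-sided via the absolute
difference of means and deterministic per seed. Spearman's rho is computed
explicitly as the Pearson correlation of mid-ranks (ties averaged), with
`stats::cor(..., method = "spearman")` serving only as a test cross-check.

## The herd simulator

The simulator is a test harness producing data with the statistical
signatures the pipeline must handle, not a claim about equine locomotion.
Movement integrates at 1 s Euler steps (overdamped; forces are velocities):

* **Attraction–repulsion spring.** Each dyad has an equilibrium distance
  `eq = equilibrium_dist_m * (1 + 2 * (1 - affinity))` (3 m at affinity 1 by
  default, mirroring the ~3 m personal-space scale of horses); the spring is
  repulsive inside it and attractive beyond it, with gain scaled by squared
  affinity, capped at 0.5 m/s per pair, and averaged over partners so
  cohesion does not grow with group size.
* **Personal space.** Every neighbour inside 2.5 m is pushed away with a
  graded force (gain below the violation depth, so no overshoot
  oscillation), with an extra ramp below 1 m; the summed evasion is capped
  at 0.7 m/s, far below the 85 cm/s charge threshold.
* **Grazing anchors.** Each agent relaxes (capped 0.3 m/s) toward a private
  anchor performing a slow reflected random walk through the enclosure;
  anchors of high-affinity dyads (> 0.6) are spring-coupled toward the pair
  equilibrium so preferred partners graze together while unrelated animals
  drift apart. A pure spring + jitter herd cannot show enclosure-dependent
  spacing without motion fast enough to confound the event detector; the
  anchors supply slow dispersal instead.
* **Feeder bouts.** With a feeder configured, agents enter Markov feeding
  bouts (start 0.001/s, stop 0.01/s) during which they walk toward the
  feeder at 0.5 m/s, producing feeder-driven co-proximity for the feeder
  filter to remove.
* Motion jitter is isotropic Gaussian (sd 0.10 m/s per axis per step);
  background speed is capped at 300 cm/s, comfortably below the 800 cm/s
  error cap so ordinary motion never trips the error filter. Boundaries are
  reflective. All randomness flows from one seed; identical configurations
  and seeds are bit-identical.

**Scripted agonistic episodes** override the forces for the involved dyad:
the aggressor walks to a charge start point (3–5 m from the target), charges
straight at 95–130 cm/s until within 150 cm, and the target then flees
directly away for 3 s at 120 cm/s (high-intensity) or 40 cm/s
(low-intensity) — by construction satisfying all four approach criteria and
cleanly separating the retreat classes. Because "two animals only" is one of
those criteria, an episode only launches when a corridor with sufficient
clearance from bystanders exists; while an episode waits, neighbours of the
intended target drift off (pre-conflict agitation), bystanders scatter from
a running confrontation at speeds far below the charge threshold, and an
episode that finds no clear corridor within 60 s is skipped and logged.
Recovery metrics therefore score against *executed* episodes.

**Sensor model.** Each dyad's true distance feeds two directed channels with
shared ranging jitter (sd 2 cm) plus independent per-channel noise (sd 3 cm,
so the channel difference has sd `sqrt(2) * 3` cm), and artifacts: spikes
above the enclosure diagonal (p = 0.001/sample), impossible readings below
5 cm (p = 0.0005), and stuck-value segments; each injected artifact is
logged for filter scoring.

What the simulator does *not* emulate — gait and orientation, terrain,
wall-following, sensor clock drift, diurnal routines — bounds what passing
tests show: they validate the pipeline's rules and statistics on data with
realistic structure, not the biology of any particular herd.

## Study-style scenarios and problem sizes

`study_scenario()` provides the two default conditions: a 30 × 15 m paddock
(8 horses, hay feeder, scripted approaches at 2.6 per horse-hour) and a
115 × 60 m field (same roster, no feeder, 0.54 per horse-hour) — episode
rates of the magnitude typical of crowded versus spacious turn-out. Under
these defaults the simulated pooled median comes out near 8 m in the paddock
and substantially larger (roughly 16–38 m depending on seed) in the field,
with the relative distance inverted — the spacing phenomenology the pipeline
is designed to quantify. The test suite
runs one-to-three-hour simulations with 6–10 agents (e.g. the event-recovery
benchmark schedules 200 episodes over 3 h with 10 agents); these sizes give
stable qualitative contrasts while keeping a full run on one CPU within a
few minutes.

## Known limitations

* Exact published medians, CIs and centrality values cannot be reproduced
  without the raw tracking data, which is not deposited; property-based
  checks (oracle equivalence, ground-truth recovery, qualitative contrasts)
  stand in for them.
* The printed space-per-horse table mixes rounding conventions (one entry is
  truncated rather than rounded); the package rounds half-up and documents
  the one-ulp disagreement.
* Event-type vocabulary is limited to the three rule-defined classes;
  distinguishing, e.g., play-fighting from true fighting needs richer
  signals than scalar dyadic distances.
* The coin-style standardised Z statistics reported alongside published
  permutation tests are not reimplemented; the test returns the raw mean
  difference and Monte-Carlo p.
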