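# equiprox

Analysis of equine social spacing and agonistic dynamics from
ultra-wideband (UWB) proximity sensors.

Group-housed horses negotiate a trade-off between affiliation and personal
space, and the room they have to do so depends on enclosure size. UWB
real-time location systems measure the distance between every pair of
head-mounted sensors once per second, turning that negotiation into 1 Hz
dyadic distance streams. `equiprox` is for behavioural ecologists and
welfare researchers who want to go from those raw streams to interpretable
social metrics:

* **Cleaning** — remove readings above the enclosure diagonal or below
  5 cm, stuck-sensor runs (> 10 s without variation), and samples where
  both horses crowd the hay feeder; then average the two directed channels
  (technical replicates) per dyad.
* **Spacing** — per-dyad median interindividual distance *d* (cm) with
  bootstrap CIs, and the *relative* distance *d / s*, where
  *s* = enclosure area / number of horses (m² per horse). Low absolute but
  high relative distance indicates forced proximity; low/low indicates
  voluntary proximity.
* **Associations** — fraction of time per dyad at ≤ 3 m, (3, 6], (6, 9],
  (9, 12] and > 12 m; each horse's closest and least frequent associate.
* **Networks** — connect dyads whose mean distance falls strictly below
  the median of all dyad means; report degree, unnormalized pairs-once
  betweenness, and closeness as reciprocal summed path length over the
  reachable component (isolated nodes score 0).
* **Agonistic events** — an approach is a ≥ 100 cm decrease to < 200 cm
  within 3 s at a mean closing speed ≥ 85 cm/s, involving exactly two
  horses, with consistent direction; retreats are ≥ 100 cm rises within
  3 s after an approach, high-intensity if they meet the 85 cm/s floor.
  Steps beyond 800 cm/s are sensor errors and are excluded. Rates are
  events / (horses × hours).
* **Inference** — Monte-Carlo Fisher–Pitman permutation test (difference
  of means, add-one corrected) and explicit mid-rank Spearman correlation.
* **Simulator** — an attraction–repulsion herd model (per-dyad equilibrium
  distances scaled by affinity, graded personal-space repulsion, slowly
  wandering grazing anchors, optional feeder bouts) with choreographed
  approach/retreat episodes and a UWB noise model. It emits raw streams
  plus ground truth for every stage, so the whole pipeline is testable
  without the original tracking data.

## Worked example

Simulate a cramped paddock condition (30 × 15 m, 8 horses, hay feeder,
scripted agonistic episodes), clean it, and quantify it:

```r
library(equiprox)

sco <- study_scenario("paddock", n_agents = 8, duration_s = 3600, seed = 2024)
sim <- simulate_herd(sco$sim)
raw <- trajectories_to_distances(sim)
cl  <- clean_distances(raw$distances, sco$enclosure)

group_summary(cl$series, sco$enclosure, "paddock", seed = 2024)$pooled
#>   condition n_dyads median_cm  ci_lo  ci_hi relative_cm_m2 space_m2_per_horse
#> 1   paddock      28     836.1  782.0  896.5          14.86              56.25
```

The 28 dyads sit at a pooled median of ~8.4 m; dividing by the 56.25 m²
available per horse gives a relative distance of ~14.9 cm/m² — the
forced-proximity signature of a small paddock (the same herd in a
115 × 60 m field shows a much larger median but a far smaller relative
distance).

```r
ev <- detect_agonistic_events(cl$series)
table(ev$kind)
#> approach high_retreat  low_retreat
#>       18            1           17
head(ev[, c("kind", "a", "b", "t_start", "t_end", "mean_speed_cm_s")], 1)
#>       kind   a   b t_start t_end mean_speed_cm_s
#> 1 approach H02 H05     211   214            93.1
event_rate(18, n_horses = 8, tracking_hours = 1)
#> [1] 2.25
```

Eighteen approaches in one hour is 2.25 approaches per horse-hour, and each
detected window carries its displacement and mean speed. Against the
simulator's ground truth this detector recovers scripted episodes with 100%
precision and recall.

```r
net <- build_social_network(cl$series, sim$ids)
net
#> <social_network: 8 nodes, 14 edges, threshold 867.6 cm>
head(net$centralities, 3)
#>   node degree betweenness closeness
#> 1  H01      3        1.17     0.091
#> 2  H02      5        5.83     0.111
#> 3  H03      5        7.83     0.111
```

## Analysis workflow

`analysis/01_simulate.R` … `analysis/07_stats.R` run the staged workflow
(simulate → clean → distance metrics → associations → networks → events →
inference) over a paddock and a field condition, writing table-shaped CSVs,
GraphML networks and a stats JSON under `results/analysis/`. Each stage
reads the previous stage's CSV intermediates, so stages can be rerun
independently. `run_pipeline()` offers the same chain as a single
configured, seeded call driven by a YAML config (`validate_config()`).

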