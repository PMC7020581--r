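---
title: "Methods: time-scaled hull home ranges for central-place foragers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-scaled hull home ranges for central-place foragers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hullrange)
```

# The analysis

`hullrange` implements a fine-scale home-range analysis for GPS-tracked
central-place foragers — animals such as grey seals that make repeated
round trips from a fixed site (a breeding and haul-out colony) to
offshore foraging patches. The chain is:

1. **Quality filtering.** Fixes acquired from fewer than 5 satellites,
   with residual error above 30, or implying travel faster than
   10 km h⁻¹ are removed. The speed rule runs in a single forward pass
   against the last *retained* fix, so a lone outlier cannot cascade
   into deleting the remainder of a track, and refiltering a filtered
   track is a no-op. Each removed fix is attributed to the first rule
   that fired (satellites, then residual, then speed).
2. **Projection.** Tracks are projected to planar metres with an
   azimuthal equidistant projection centred on the colony (sphere of
   mean radius 6 371 008.8 m). For a colony-centred study this
   minimises distance distortion where it matters; pairwise distances
   within 500 km of the centre are preserved to better than 0.5%.
3. **Movement states.** A two-state hidden Markov model on travel rate
   (gamma emissions; state 1 slow by convention) is fitted by
   Baum–Welch EM. The forward recursion restarts at every burst, where
   bursts are separated by inter-fix gaps above 2 h — the tags suspend
   GPS attempts when dry, so haul-outs appear as gaps and must not
   contribute spurious speeds. The smoothed posterior probability of
   the slow state is reported as p(ARS), the probability of
   area-restricted search (apparent foraging or resting); its
   complement indicates travel.
4. **Hulls.** One convex hull is built around every fix (the parent)
   from neighbours selected under the time-scaled distance
   TSD = sqrt(dx² + dy² + (s · v_max · dt)²), either the k nearest
   (k-method) or, by default, all neighbours whose cumulative TSD stays
   under a limit `a` (adaptive method, which gives small hulls where
   the animal moved slowly and generated dense data). With s = 0 the
   TSD is the plain planar distance and time plays no role.
5. **Isopleths.** Hulls sorted by point density (enclosed fixes per
   km²) and merged until 95% of fixes are covered give the seasonal
   home range; hulls sorted by the number of separate visits (nsv) and
   merged until 30% coverage give the conservative core area of
   repeatedly revisited habitat. Coverage counts fixes uniquely across
   the growing union.
6. **Per-hull behaviour metrics.** nsv (a new visit begins after more
   than 12 h outside the hull — a gap of exactly 12 h does not split a
   visit), mean locations per visit (mnlv), their area-normalised
   versions, the eccentricity of the minimum-area enclosing ellipse
   (0 circle-like/exploitative, 1 line-like/ballistic), and the mean
   p(ARS) over enclosed fixes.
7. **Six behaviour categories.** Pooling all animals' hulls, the first
   and third quartiles of nsv km⁻² split hulls into infrequent,
   frequent and very-frequent visitation bands; each band splits again
   at its own median of mnlv km⁻² (ties to the lower-duration
   category), giving categories 1–2, 3–4 and 5–6. Category 6 marks the
   most-revisited, longest-occupied habitat. Hulls whose parent lies
   within 15 km of the colony are excluded from classification and
   time budgets (near-colony milling would dominate the quantiles);
   home ranges and core areas are unaffected by this exclusion.
8. **Statistics.** Candidate linear mixed models (animal identity as a
   random intercept, ML fits so likelihoods are comparable across
   fixed-effect structures) are compared with AICc, ΔAICc, Akaike
   weights and evidence ratios; marginal and conditional R² come from
   the fixed / random-intercept / residual variance decomposition.
   Spread is summarised as the raw median absolute deviation (no
   1.4826 consistency factor). Mass gain is expressed as percent of
   initial mass per day, with post-parturition females corrected back
   to parturition mass at 4.1 kg day⁻¹.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_sats` / `max_residual` / `max_speed` | 5 / 30 / 10 | – / – / km h⁻¹ | fix quality rules |
| `gap_threshold_h` | 2 | h | burst segmentation (8 missed 15-min fixes) |
| `s` | 0.05 | – | time scaling of the TSD; chosen per animal so 40–80% of hulls are time-selected (`time_selected_fraction()`); 0.03–0.10 is the typical band for seal-like tracks |
| `v_max` | derived | m h⁻¹ | 99.9th percentile of observed speeds, capped at the 10 km h⁻¹ filter bound |
| `k` | 15 | – | neighbour count anchoring the adaptive limit `a_k15` (`a_for_k()`) |
| `a` | derived | m | cumulative-TSD limit; candidates centred on `a_k15`, chosen where the 95% isopleth area stabilises (first relative change < 10%, `isopleth_diagnostics()`) |
| `ivg_h` | 12 | h | minimum absence separating return visits |
| isopleth levels | 0.95 / 0.30 | – | home range (density-sorted) / core (visit-sorted) |
| colony exclusion | 15 | km | classification and time budgets only |
| `min_fixes` | 100 | – | minimum fixes per season for a seasonal isopleth |

A hull is *time-selected* when its neighbour set under the working `s`
differs from its neighbour set at s = 0; the recommended `s` is the
smallest candidate putting 40–80% of hulls in that state. The
stabilisation threshold for k/a makes an otherwise by-eye judgement
("choose the value where the isopleth area stabilises") explicit and
testable.

# The synthetic population

Real tracking data of this kind are archived under controlled access,
so the package ships a seeded generator whose defaults emulate the
study conditions the analysis assumes: GPS fixes every 15 min across a
1 June – 4 December window split into summer (through 30 September) and
fall (through 4 December); repeated trips from a colony to shallow
offshore banks (bank depths 50–75 m, within ~150 km); directed fast
travel; slow, high-turning area-restricted search at a small set of
repeatedly revisited patches; haul-outs at the colony during which the
(dry) tag records no fixes.

Movement is a mode-switching correlated random walk whose structure was
chosen so that the two movement states are identifiable by the HMM and
so that revisitation has a genuine fine-scale signal for the hull
metrics to find:

* **Travel** is a biased correlated walk (heading a mixture of the
  previous heading and the bearing to the goal, `travel_bias = 0.25`,
  gamma speeds of mean 4 km h⁻¹): successive trips take distinct,
  meandering routes, as real commutes do, rather than retracing one
  line.
* **Foraging** is a centre-attracted (Ornstein–Uhlenbeck-style) walk
  confined to the patch radius, with gamma speeds of mean 0.6 km h⁻¹
  and heavy turning. Within a visit the animal works the bank's best
  spot in bouts — station-keeping within ~10% of the patch radius for
  6 h out of every 20 h cycle, ranging over the wider bank in between.
  The bout structure mirrors cyclic benthic foraging and produces
  within-visit absences of more than 12 h from the hotspot, which is
  what makes hotspot hulls genuinely dominate the visit-frequency
  ranking (corridor hulls near the colony are crossed on every trip,
  but their coverage is small).
* **Scheduling.** Forage dwell per trip is drawn from a tight gamma
  whose mean is set so the at-sea time split matches `forage_frac`
  (default 60% foraging / 40% travel) given the animal's mean
  round-trip commute — dwell reflects satiation, not that trip's
  commute length. Between trips the animal hauls out for ~12 h; patch
  choice follows attractiveness weights with the last-visited bank
  down-weighted (prey renewal), so each animal rotates among its
  preferred banks.
* **Population structure.** Each animal specialises on two banks drawn
  from its sex's pool — males from a farther, larger set (60–150 km),
  females nearer (30–80 km) — and in fall both sexes contract onto the
  nearest available banks. This yields the qualitative population
  patterns the analysis should detect: larger male home ranges, fall
  contraction, strong individual site fidelity.
* **Defects.** `inject_defects()` flags disjoint random fixes with low
  satellite counts, high residuals, or 8–20 km teleports (rates
  1.2% / 1.5% / 5%, together ~7.7%), with truth labels retained so
  filter fidelity is measurable.

What the generator does **not** emulate: position error on retained
fixes (clean fixes are exact), tides and currents, depth-driven
behaviour (bathymetry is decorative for the movement model), partial
migration off the shelf, haul-outs away from the colony, and
between-year variation. Passing tests therefore show that the
implementation recovers structure *of the kind assumed by the method*
from data that contain it — not that real seal data contain such
structure, and not that the published medians would be reproduced
(those depend on the original dataset, and the synthetic setting is
deliberately scaled down: population home ranges here are
O(100–400 km²), not thousands).

# Numerical choices

* **Projection**: spherical azimuthal equidistant; exact analytic
  inverse (round-trip error is floating-point noise).
* **Gamma EM**: zero speeds are nudged to half the smallest positive
  speed (gamma support is open at zero); emissions are re-estimated by
  weighted ML with a Newton solve of the shape equation; the initial
  state distribution is tied to the stationary distribution of the
  transition matrix; convergence at |ΔlogLik| < 1e-6, cap 500
  iterations; deterministic 2-means initialisation, so a seed changes
  nothing in the default path. Label switching is resolved by ordering
  states by emission mean (slow first).
* **Neighbour ties** (equal TSD) break by fix index; **isopleth ties**
  (equal sort metric) by smaller hull area, then earlier parent time —
  all deterministic.
* **Degenerate hulls** (fewer than 3 distinct, non-collinear members)
  carry zero area, eccentricity 1 by convention, and are excluded from
  isopleth accounting and classification.
* **Polygon unions** use the Clipper library (`polyclip`), with areas
  by the shoelace formula over the returned rings (holes subtract);
  point-in-polygon tests are boundary-inclusive, so hull members are
  always enclosed by their hull.
* **Enclosing ellipse**: Khachiyan's barycentric ascent, tolerance
  1e-7; for collinear input the minor axis collapses and e = 1.
* **Quantiles** are linear-interpolation sample quantiles (R type 7);
  the median split assigns ties to the lower-duration category.
* The core (30%, visit-sorted) is *not* asserted to nest inside the
  95% density-sorted home range: the two isopleths sort by different
  metrics, so non-nesting is possible and documented behaviour.

# Design decisions on open points

* The TSD functional form (time as a third Euclidean axis scaled by
  s · v_max) is the standard published form; the source study describes
  it without printing the formula.
* "Density of data points" is enclosed fixes divided by hull area, and
  isopleth coverage counts fixes uniquely across the union — the two
  readings (member vs enclosed counting; summed vs unique) differ only
  in tie-heavy corners, and the unique/enclosed pair is the one that
  makes coverage a true fraction of the track.
* The speed filter is applied in a single forward pass (not iterated to
  a fixed point): telemetry practice, deterministic, and idempotent.
* Season boundaries are inclusive as listed; dates after 4 December
  map to an `excluded` season rather than an error, since the at-sea
  study effectively ends when animals return to breed.
* Mixed-model internals are delegated to `lme4` (ML, not REML); the
  package owns everything downstream of (LL, K, n, variance
  components). K counts fixed coefficients plus the random-intercept
  and residual variances.
* The per-band duration thresholds are within-band medians — the only
  reading that yields one threshold per visitation band.
* Problem sizes used by the test-suite and acceptance runs (a 6-animal,
  90-day population; 20 HMM replicates of 2 000 steps; 50
  model-selection replicates of n = 80) were chosen as the smallest
  sizes at which the targeted effects are comfortably identifiable.

# Known limitations

* Isopleths are supported at the two seasonal windows only; no
  finer temporal isopleths.
* No fixed-radius (r-method) neighbour selection and no kernel
  utilisation distributions.
* The a-limit is held fixed across an s-sweep only when supplied
  explicitly; when derived, it is re-derived per s so candidates stay
  comparable — a different convention than sweeping both jointly.
* p(ARS) for the first fix of each burst is imputed from the first
  step of that burst (speeds are defined between fixes, probabilities
  are wanted per fix).
* With only two movement modes, at-sea resting and foraging are
  conflated in the slow state, exactly as in the two-state analysis the
  package implements.
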