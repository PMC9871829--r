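---
title: "Analysing mass-start ski races from GNSS tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing mass-start ski races from GNSS tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skipack)
```

## The problem

In a mass-start cross-country ski race every competitor starts at the same
gun, and the result is decided head-to-head. What matters tactically is not
absolute speed alone but *relative* position: who sits in which pack, where
skiers lose contact with the leaders, how braking waves (the accordion
effect) propagate backwards through the field, and in which terrain the time
is actually lost. skipack turns raw 10 Hz GNSS tracks plus the official
split-time table into exactly these quantities.

The pipeline is:

1. **Reference course** (`build_reference_course()`): all fixes of all
   skiers and laps are pooled into 1 m bins of arc length and averaged
   robustly (per-bin medians), giving a single 3D course line.
2. **Terrain segmentation** (`classify_terrain()`): the lap elevation
   profile is smoothed, its gradient thresholded, and short runs merged,
   yielding uphill/flat/downhill segments (S1, S2, ...).
3. **Projection** (`project_track()`): each track is map-matched to the
   course (monotone nearest point), giving a strictly increasing arrival
   time at every metre — the *trace* — from which lap and segment speeds
   follow (`speed_matrix()`).
4. **Pack dynamics** (`gap_matrix()`, `pack_timeline()`): at every grid
   distance, skiers are partitioned into packs by the rule that consecutive
   arrival gaps under 3 s keep a pack together (strictly less than 3 s; a
   gap of exactly 3.0 s splits). Pack identities are carried along the
   course by member overlap, and split/merge events are recorded.
5. **Accordion metrics** (`accordion_summary()`): counts of skiers within
   {1, 5, 10, 30, 60, 90, 120} s of the current leader, and a per-skier
   exposure index counting deceleration–reacceleration cycles.
6. **Pacing statistics** (`lap_speed_comparisons()`,
   `time_loss_decomposition()`): one-way ANOVA with Tukey post-hoc
   comparisons between performance groups and laps, time-in-terrain shares,
   and the decomposition of time lost to the leading group by terrain type.
7. **Profile synthesis** (`fit_profile_model()`, `synthesize_trace()`):
   a full distance–time trace for a skier who has only official splits,
   reconstructed from the within-interval pacing shapes of the most similar
   peers.

All gaps are computed in the **distance domain** — the difference in arrival
time at the same course distance — which matches split-time semantics. Time-
domain gaps (distance between skiers at the same instant) would mix terrain
into every comparison.

## The synthetic race generator

Real races of this kind are rarely deposited as raw data, so the package
carries a seeded agent-based simulator (`generate_course()`,
`simulate_race()`) that emulates the statistical structure the analysis
assumes and returns full ground truth (true splits, segment times, pack
partitions, event logs). Every accuracy claim in the test suite is a
round-trip against this truth.

### Course

The default lap mirrors a national-level venue: a 3,550 m loop with 14
terrain segments, 114 m climb per lap, a 42 m height difference, and
uphill/flat/downhill distance fractions of 37.2/20.4/42.4 %. Removing the
steepest downhill (S5, −12 %) and its return climb (S6) leaves the 3,170 m
first-lap variant with 93 m of climb. Geometrically the loop is laid out as
a circle of the right circumference in a local planar frame (east/north
metres, anchored at a typical Nordic venue latitude for GPX export);
elevation is piecewise linear per segment plus a smooth periodic undulation
of at most 0.5 m. One simplification is deliberate: **all six laps run the
identical full loop**. The real Lap 1 was a physically distinct shorter
course; here the Lap-1 course is represented analytically — `speed_matrix()`
drops the excluded segments from Lap-1 rows and aggregates — because a
per-lap geometry branch would break the single closed-loop course model that
projection relies on.

### Skiers

Each skier has a flat cruise speed (`ability`, default 7 m/s for the top
seed, declining 0.005 m/s per start position), gradient responses
(speed × 1/(1 + 0.115 g) uphill, × min(1 + 0.055 |g|, 1.8) downhill, g in
percent — about 3.6 m/s on an 8 % climb and 11.6 m/s on a −12 % descent,
in the range seen in elite skating races), and a per-lap fatigue rate that
grows superlinearly with start position (power 1.8). That last choice makes
the front ten hold their lap speed within ~1 % over laps 2–6 while the back
of the field fades lap by lap and sheds progressively from the rear — the
canonical mass-start pattern of a stable leader pack and dropping chase
groups.

### Behaviour

* **Following**: a skier within 8 s of the one ahead will ride up to
  `follow_gain` (5 %) above natural pace to close; within 0.4 s they lock to
  the leader's speed rather than overrun.
* **Drafting**: within 3 s of the skier ahead, speed gains
  `drafting_saving` (1.5 %).
* **Accordion**: each time the race leader enters an uphill segment, a
  braking wave is scheduled backwards: the skier at field position *p* is
  slowed by min(0.5, 0.008 (p−1)) for 2 s, starting 0.3 (p−1) s after the
  trigger. This reproduces the backward propagation and rearward
  amplification of decelerate–accelerate waves; magnitudes are configuration,
  not empirical claims.
* **Incidents**: at each lap crossing, skiers behind field position 10 have
  a 2 % chance of a 4 s obstruction.
* **Congestion**: no overtaking in the first 400 m; the start grid spaces
  bibs 1 m apart, so the line is crossed up to ~7 s after the gun at the
  back.

With all behaviour switched off the model is exactly integrable, and the
simulator agrees with the closed-form finish times to 0.1 % (this is a unit
test). A fixed seed reproduces the race bit for bit.

## Numerical choices

* **Seed path and arc length.** The course's arc-length parameterisation
  comes from one clean track: positions are smoothed over 2 s with
  point-symmetric edge padding (plain reflection would bias the endpoints
  inward and shift the course origin by several metres), downsampled to
  ~10 m before measuring length (raw 0.7 m steps of 2 m-noise fixes would
  inflate arc length as a random walk), and cut at the continuously refined
  loop closure. The final node spacing is re-measured on the median
  polyline, so lap length does not inherit seed-track noise: with forty
  tracks at 2 m noise the default lap is recovered at 3,550 m exactly and
  node positions to better than 0.1 m RMS.
* **Map matching** is a monotone nearest-point match with a bounded per-fix
  advance (6 m per 0.1 s) and a 15 m corridor, implemented in C++. The
  monotone constraint prevents snapping across spatially adjacent but
  distant-in-arc-length sections of a looped course; the bounded advance
  keeps a noisy fix from teleporting a lap ahead. Reversed or off-course
  tracks fail a 90 % coverage check rather than being silently projected.
* **Segmentation defaults** (30 m smoothing, ±2 % thresholds, 50 m minimum
  segment) reproduce the 14 segments of the default course with boundary
  errors under 10 m; all three are exposed as arguments because the
  procedure is otherwise under-determined.
* **Pack rule boundary.** "Less than 3 s" is implemented strictly: a gap of
  exactly 3.0 s starts a new pack. The pack detector is tested against a
  brute-force oracle on a thousand random fields with salted exact-boundary
  gaps.
* **Losing the leader pack** is operationalised as: first grid point at
  which the skier is outside the pack containing the current leader and
  stays outside for at least 200 m (detachments right before the finish
  also count). The sustain rule suppresses flicker at the 3 s boundary.
* **Start-line anchoring in profile synthesis.** Official splits do not
  record when a skier crosses the start line, but in a mass start the back
  rows cross seconds after the gun. The profile model therefore regresses
  the crossing delay on the first checkpoint time over the training skiers
  and anchors the first interval there; without this, reconstructed traces
  mis-place up to ~6 s around the start.

## What the simulator does and does not show

Passing the round-trip suite shows the pipeline recovers what the generator
encodes: terrain-dependent speeds, fatigue heterogeneity, follow/draft pack
cohesion, backward-propagating braking waves, and GNSS noise of the assumed
magnitude. Real races add things the generator does not model: curvature
and technique-dependent downhill lines (laps do not overlap perfectly in
space), multipath and canopy-dependent GNSS error (not white), snow
transformation over the race, and genuinely strategic behaviour (attacks,
deliberate pace changes). Results on real data therefore need the
split-time validation step (`validate_against_splits()`) that the reference
study also used, rather than being guaranteed by these tests.

Known limitations:

* Profile synthesis reconstructs what peers' splits can express. Individual
  episodes — a crash, a broken pole, a solo drop between two checkpoints —
  are invisible in 17 splits; reconstruction error for tail-enders with
  pack-dependent stop-go patterns can exceed the ~2 s typical of front and
  mid-field skiers. Synthesised traces are for pack dynamics only and are
  excluded from speed statistics, mirroring how such skiers are handled in
  practice.
* Relative positions *within* a pack are not resolved (GNSS is not accurate
  enough for that in the field), so the simulator's within-pack order should
  not be interpreted.
* The comparison layer applies Tukey's correction within each ANOVA but no
  correction across the many lap × segment × group tables, matching common
  practice in the field; treat isolated significances accordingly.

## Problem sizes used in the checks

The acceptance suite and `scripts/acceptance.R` run: one noiseless and one
2 m-noise race at the full study scale (40 skiers, 6 × 3,550 m laps, 10 Hz,
17 checkpoints); fifty 24-skier, 2-lap replicate races for the accordion
exposure contrast; a thousand random fields for the pack oracle; five
hundred replicates each for the null-calibration and power checks of the
comparison layer (two groups of ten, SD 0.1 m/s, offset 0 or 0.3 m/s); and
five held-out skiers (final ranks 3, 7, 8, 18, 26 — the ranks synthesised
in the reference race) for profile reconstruction. These sizes were chosen
as the smallest that exercise the study conditions faithfully.

## A worked example

```{r example, eval = FALSE}
spec <- course_spec()
course <- generate_course(spec, seed = 1)
field <- make_skiers(40, seed = 2)
race <- simulate_race(course, field, sim_config(seed = 3, gnss_noise_sd = 2))

est <- build_reference_course(race$tracks, n_laps = spec$n_laps)
segs <- classify_terrain(est)
traces <- project_tracks(race$tracks, est)

gm <- gap_matrix(traces)
packs <- pack_timeline(gm)
groups <- assign_groups(race$ranks)
acc <- accordion_summary(gm, groups = groups)

sm <- speed_matrix(traces, segs, lap1_excluded = spec$lap1_excluded_segments)
time_in_terrain(sm)$mean
time_loss_decomposition(sm, groups)
start_finish_correlation(race$ranks)

plot(course)                     # lap profile with terrain segments
plot(gm, groups = groups)        # time behind the current leader
```
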