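---
title: "Methods: quantifying worm locomotion and plate chemotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying worm locomotion and plate chemotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nematrack quantifies the behaviour of nematodes crawling on assay plates
from two kinds of raw data: per-animal tracker exports (time-stamped
centroid and head-tip coordinates) and per-plate endpoint counts from
two-point odorant assays. This vignette documents the measures, the
detection procedure, the statistical layer, and the design decisions behind
them. Internal units are millimetres and seconds everywhere; thresholds
quoted in other units (cm/s, µm/s) are converted once, at the interface.

```{r setup}
library(nematrack)
```

## The chemotaxis index

A two-point assay places an odorant spot and a solvent-control spot on
opposite sides of a 5-cm plate, each with sodium azide so that arriving
worms are fixed in place. At the end of the assay each worm is assigned to
the control half (count $A$), the odorant half (count $B$), or a central
1-cm-wide exclusion band (count $C$, reported but never scored). The
chemotaxis index of a plate is

$$\mathrm{CI} = \frac{B - A}{A + B} \in [-1, 1],$$

so $+1$ is complete attraction and $-1$ complete avoidance. Two design
rules follow the way such assays are analysed in practice:

* **The per-plate CI is the statistical unit.** Group summaries and tests
  operate on the distribution of per-plate indices (the quantity shown in
  the usual boxplots), not on pooled counts; `pooled_chemotaxis_index()`
  is available as a secondary descriptive output.
* **Counts are odorant-anchored.** Benches alternate the physical
  left/right position of the odorant across trials to cancel spatial bias.
  `assign_zones()` therefore normalises sides at scoring time: $B$ is
  always the odorant zone, whatever the physical side, and a mirrored
  plate yields identical counts by construction.

A plate with $A + B = 0$ cannot be scored; it is flagged `scorable =
FALSE` and excluded from statistics with a logged notice, rather than
being given an arbitrary index.

## Track kinematics

A track is an ordered series of frames (time, centroid, head tip) with an
in-band validity flag; tracking dropouts stay in the series as
`valid = FALSE` frames. All measures are built from *steps* between
consecutive frames, and a step is usable only when both of its endpoint
frames are valid. Gap steps are excised, never interpolated: bridging a
gap with a straight segment would fabricate path length and bias the
head-swinging index downward.

* **Instantaneous speed** is the frame-to-frame centroid displacement
  divided by the actual inter-frame interval.
* **Median speed** is the per-animal median of instantaneous speeds after
  excluding gaps and immobile steps (speed `< 0.2` mm/s, i.e. 0.02 cm/s;
  the exclusion is strict, so a step exactly at the threshold survives).
  When every step is immobile the animal is flagged `immobile` rather
  than assigned a median of zero.
* **Outlier rule.** Plate trackers segment worms reliably only up to about
  500 µm/s, so *individuals* whose median speed exceeds 0.5 mm/s are
  excluded from statistical analysis (`apply_outlier_filter()`), with the
  exclusion logged. The rule removes animals, not frames: a per-frame
  cut would censor the fast tail of each speed distribution and bias the
  medians of the animals that remain. Exactly 0.5 mm/s is kept ("up to"
  the ceiling is trackable).
* **Track length** is the summed Euclidean step distance over valid steps.
* **Head-swinging index** is head-track length divided by centroid-track
  length, computed over the identical step-validity mask. It is 1 for a
  head rigidly leading a straight-moving centroid, grows with lateral
  head oscillation, is dimensionless and scale-invariant. A track whose
  centroid never moves has no defined index; the animal is flagged (error
  class `nematrack_undefined_index`), not silently dropped.

Positional jitter inflates both path lengths. No smoothing is applied by
default — smoothing also erodes genuine head oscillation — but an optional
moving-average smoother (`smooth_track()`, gap-respecting, window
configurable) is provided and logs its use.

## Pirouette detection

Pirouettes — the reversal/omega-turn complexes worms use to redirect runs
— are detected from the centroid trajectory only (head oscillation must
not enter the turning signal). The criterion: the cumulative turning angle
exceeds 120° within a window of at most 3 s, accompanied by a concurrent
speed drop of at least 40% relative to the animal's 2-s pre-event
baseline, the baseline being anchored immediately before the window start.

Step headings come from the `atan2` of the centroid displacement, and turn
increments are wrapped successive heading differences in $(-180°, 180°]$.
The detector scans every sub-interval of contiguous usable steps with
duration between `min_duration` and `window`, and a candidate fires when
both criteria hold. Overlapping or abutting candidates, and candidates
closer than 1 s, are one behavioural event: the merged event reports the
candidate with the largest $|$net turn$|$ (ties broken by the larger speed
drop, then the earlier start), so one omega-turn is never counted twice.
Per-animal rates are events per minute of *valid* observation time, so
tracking gaps do not deflate them.

Numerical and design choices that matter:

* **Net, not absolute, turning (default).** "Cumulative turning angle" is
  read as the magnitude of the net signed sum of wrapped increments. A
  sum of absolute increments fires on vigorous side-to-side oscillation
  without any reorientation — which would make a slow, high-head-swinging
  worm look pirouette-rich, the opposite of what reorientation measures
  are for. Both readings are implemented (`mode = "net" | "absolute"`);
  results record which mode produced them.
* **Heading floor (`min_step = 0.01` mm).** Below ~10 µm of displacement
  the direction of motion is at jitter scale and a heading is
  meaningless; such steps are masked and windows cannot span them.
* **Minimum event duration (`min_duration = 0.8` s).** A pirouette is an
  extended manoeuvre; an apparent near-instant heading flip at
  plate-camera resolution is positional jitter, not behaviour. At 10 fps
  with realistic (~20 µm) jitter, the apparent per-step displacement is
  jitter-dominated, and one- or two-step "reversals" satisfy both the
  angle and the drop criterion thousands of times per hour; windows of
  0.8 s and longer cannot sustain both criteria by jitter alone (the
  measured false-positive rate at 20 µm jitter drops from ~10/min to
  below 0.01/min) while recovery of injected 1-s events is unchanged.
  The value was chosen, once, from this characterisation.
* **Baseline with gaps.** The 2-s baseline mean uses valid steps only and
  requires at least half of its steps valid; otherwise the candidate is
  skipped (logged), not an error. Where the baseline should be anchored
  is ambiguous in the field's verbal definitions; window-start anchoring
  is used and stated.

The windowed implementation is validated against an exhaustive
$O(n^2)$ sub-interval oracle (plain nested loops, independent code path)
with exact event-set equality required after merging, and against
generator ground truth by rate recovery.

## The synthetic worm generator

`simulate_track()` produces a correlated random walk with known ground
truth, which is what makes every stage of the pipeline testable by
parameter recovery:

* step speed: lognormal AR(1) with mean `mean_speed`, coefficient of
  variation `speed_cv`, lag-1 autocorrelation `speed_ar1`;
* heading: integrates Gaussian turning noise of variance
  `heading_diffusion · dt` (deg²), plus pirouette reorientations injected
  as a Poisson process (`pirouette_rate` per minute). Each event adds a
  net signed turn of random sign and truncated-Gaussian magnitude (mean
  `pirouette_turn`, 10% sd, truncated below at 130° so injected events sit
  clearly above the 120° detection threshold rather than straddling it),
  spread over `pirouette_duration` while speed is multiplied by
  `pirouette_speed_factor`;
* head tip: centroid plus `head_offset` along the heading plus a lateral
  sinusoid (`head_amp`, `head_freq`, random phase);
* imperfections: iid Gaussian positional jitter (`noise_sd`) on both
  positions and iid frame dropouts (`gap_prob`).

The default frame interval is `dt = 0.1` s (10 fps), typical for
plate-scale worm tracking; recording rate is metadata the analysis never
assumes, which is why the track dialect carries `dt` explicitly. The
realised event schedule rides on the track as `$truth` and is read by
recovery *tests* only — no analysis function touches it.

Two shipped presets encode the qualitative two-species contrast the
package is built around: `species_preset("elegans")` (0.30 mm/s, small
0.08-mm/0.4-Hz head oscillation, 1 pirouette/min) and
`species_preset("inopinata")` (0.15 mm/s, larger 0.15-mm/0.6-Hz
oscillation, 0.05 pirouettes/min). Absolute numbers are self-chosen
realistic values for adults on agar — published per-species values live in
extended data tables rather than any text we could anchor to — so the
validation suite asserts only the *ordinal* relations between the presets
(slower, swingier, fewer pirouettes), and those are what the full-pipeline
check reproduces with rank-test $p < 0.05$ at $n = 20$ tracks per group.

What the generator does **not** emulate: odorant-gradient navigation (the
synthetic worms are condition-agnostic random walkers; there is no
klinotaxis steering toward a source), body posture along the skeleton,
multi-worm collisions, or identity swaps across gaps. Passing recovery
tests therefore validates the measurement pipeline, not any claim about
how real worms move; on real data the measures inherit whatever
segmentation quality the upstream tracker provides.

`simulate_plate()` draws endpoint counts from a single multinomial per
plate (probabilities `p_control, p_odorant, p_central`, default 10 worms),
so counts conserve the plate load exactly; the mean per-plate CI of such
ensembles is checked against the conditional expectation computed by
direct enumeration over all multinomial outcomes.

## Statistics

The statistical layer mirrors standard practice for these designs:
two-sided Wilcoxon rank-sum tests for pairwise comparisons (exact by the
rank-sum distribution when the combined sample is ≤ 12 without ties —
validated against full enumeration of rank assignments — otherwise the
tie-corrected normal approximation with continuity correction; ties always
force the approximation), Kruskal–Wallis with tie correction for
multi-group designs, Dunn's pooled-rank z tests post hoc, and
Benjamini–Hochberg step-up adjustment across the post-hoc family. The BH
family is deliberately the pairwise family of one analysis, not anything
wider: the adjustment belongs to the post-hoc procedure it follows.

Effect sizes are median differences with percentile bootstrap 95%
intervals (`bootstrap_median_diff()`): percentile rather than BCa because
it is the minimal, assumption-light reading of "bootstrap resampling", and
the quantity of interest is a difference of medians whose bootstrap
distribution is already centred in the designs used here. Every bootstrap
takes an explicit seed so published intervals are replayable. Degenerate
inputs (all values identical) return $p = 1$ with a warning rather than
`NaN`.

## Validation problem sizes

The test suite regenerates all of its data and runs, among others: 1,000
simulated plates against the enumeration oracle; 200 null-control plates;
50 random tracks of up to 2,000 frames for detector-vs-oracle equality; 20
tracks × 30 min for rate recovery and false-positive control; exhaustive
Wilcoxon enumeration for all no-tie configurations with $n_1 + n_2 \le
10$ plus a 5,000-replicate size check; 500 replicate studies (n = 30/30,
1,000 bootstrap resamples) for CI coverage; and the n = 20/20 two-species
pipeline. These sizes were chosen so each check has enough resolution for
its stated tolerance (e.g. three Monte-Carlo standard errors, or a ±10%
recovery band) while the whole suite stays quick enough to run on every
change. `scripts/acceptance.R` recomputes the same quantities end to end
from a single seed.

## Known limitations

* Event detection below ~1.5× the heading floor speed is unreliable by
  construction: a worm that pirouettes while moving slower than ~0.1 mm/s
  at 10 fps leaves sub-floor displacements and its turning is masked.
* The immobility filter interacts with very slow animals: an individual
  whose true median speed is near 0.2 mm/s has its reported median drawn
  from the upper tail of its speed distribution.
* Percentile bootstrap intervals for medians inherit the lumpiness of the
  sample median at small $n$; coverage is validated at $n = 30$ per group
  and should not be assumed far below that.
* The side-normalised CI assumes the odorant side is recorded correctly
  per plate; no internal check can recover a mislabelled side.
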