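---
title: "Quantifying surplus cervical joint motion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying surplus cervical joint motion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervik)
```

## The problem

During a whole-neck flexion or extension excursion, a single cervical
intervertebral joint does not necessarily move monotonically towards its
end-range. A joint can pass its eventual terminal position early in the
movement and return to it (pro-directional *surplus* motion), or finish the
excursion on the opposite side of upright altogether (anti-directional
end-range). Clinically this matters because end-range flexion/extension
radiographs are read under the assumption that end-range *is* maximum joint
motion; where surplus motion is common that assumption fails.

`cervik` implements the quantitative pipeline for this question: from 2D
sagittal osseous landmarks (typically marked on videofluoroscopy frames) to
per-joint rotation trajectories, a 10%-epoch decomposition of the
excursion, surplus statistics, a three-way motion-type classification, and
cohort-level tables and tests.

## From landmarks to joint angles

Each frame carries 26 named points: four external occiput markers (C0),
the anterior/posterior arch centers of the atlas (C1), the two inferior
corners of the axis (C2), the four endplate corners of C3–C6, and the two
superior corners of C7. (Marking protocols in this literature are often
summarised as "22 points"; the enumerated scheme implemented here contains
26 named coordinates.)

A vertebra's *midplane* is the directed line from its posterior reference
midpoint to its anterior reference midpoint; its angle is measured
counterclockwise from the horizontal and wrapped to (−90°, 90°], since a
midplane is a line, defined modulo a half-turn. The reference points use
exactly the marked landmarks, and midpoints of marked pairs where a
vertebra carries four points — a construction that is symmetric,
translation/scale-invariant and exactly rotation-equivariant (rotating a
vertebra's landmarks by θ rotates its midplane by θ). Joint rotation is
the difference between the cranial and caudal midplane angles. In the
canonical frame (x anterior, y superior) a positive rotation is extension;
a `facing` flag mirrors recordings made the other way.

Joint *position* is rotation relative to upright. The default upright
reference is the mean rotation over the initial 2 s hold
(`upright_reference = "initial-hold-mean"`), which averages marking noise;
`"first-frame"` is exact for noise-free data.

## Epochs, decomposition and surplus

The recording protocol is a 16 s excursion at 25 frames/s with 2 s holds at
upright and at end-range; `trim_holds()` removes the hold windows by the
configured durations rather than by velocity detection — the protocol fixes
the holds, and detection would add unvalidated behaviour.

`segment_epochs()` splits the trimmed excursion of N samples into ten equal
time epochs, with boundary k at sample `round(k (N−1) / 10)`
(round-half-to-even: deterministic and balanced). Cumulative boundary
positions are re-zeroed at boundary 0, so the ten per-epoch displacements
telescope exactly to the end-range.

For each record, with positions normalised so pro-directional motion is
positive:

* `end_range` — final position;
* `max_pro` — maximum cumulative position, the start counting as
  attainable (so `max_pro ≥ 0`);
* `surplus_pro = max_pro − end_range` — pro-directional surplus;
* `min_pos`/`surplus_anti` — the anti-directional extreme and its
  magnitude;
* `pro_sum`/`anti_sum` — sums of positive/negative increments, satisfying
  `pro_sum − anti_sum = end_range` identically.

Extremes are read at the *epoch-boundary* resolution by default: the
tabulated quantities of this analysis are defined on the 10% epochs, and
boundary reads are insensitive to single-frame noise spikes. Frame
resolution is available (`resolution = "frames"`) for continuous-curve
work; frame-resolution maxima are never smaller than boundary maxima.

## Motion types

* **C (Classic)** — maximum equals the terminal position.
* **S (Surplus)** — maximum exceeds the terminal position.
* **A (Anti-directional)** — terminal position below upright
  (strictly: type A requires `end_range < 0`; a joint ending exactly at
  upright is degenerate and classified C, because the A definition is
  strict).

Ties (`max_pro ≤ end_range + epsilon`) classify as C with `epsilon = 0` by
default: published surplus values as small as 0.02° indicate that near-ties
were treated as genuine surplus, so no tolerance is imposed on clean data.
For noisy recordings two documented controls exist: `boundary_window`
averages 2w+1 frames around each epoch boundary (noise sd shrinks by
√(2w+1)), and `recommended_epsilon(noise_sd, window)` applies a three-sigma
tolerance on the difference of two boundary readings,
`3·√2·noise_sd/√(2w+1)`. Joints that move anti-directionally from the
outset and never pass upright pro-directionally are flagged `never_pro`
(maximum over all non-start samples ≤ 0) and reported alongside type A.

## Cohort tables

`type_proportions()` reports counts and percentages (1 decimal).
`surplus_statistics()` gives mean, sample SD (n−1) and range of the type S
pro-directional surplus by level, region (upper = C0/C1–C2/C3, lower =
C3/C4–C6/C7) or pooled; single-record groups report SD 0 with an explicit
n = 1 flag so tables keep their shape.

`quartile_table()` ranks type S records per level by end-range magnitude
and assigns rank r of n to quartile `floor(4(r−1)/n) + 1`. For n not
divisible by four this places the remainders in the *low* quartiles,
keeping the smallest end-ranges in quartile 1 (with n = 5 the quartile
sizes are 2, 1, 1, 1). Each quartile reports the mean surplus in degrees
and the mean of per-joint percentages `100·surplus/|end_range|` — the mean
of ratios, not the ratio of means, since the per-joint percentage is the
clinically interpreted quantity; zero end-ranges are excluded from the
percentage mean and counted. When surplus is independent of end-range the
percentage necessarily falls from quartile 1 to quartile 4 (the
denominators grow), which is the pattern this analysis is designed to
exhibit.

`anti_directional_table()` reports, per level, the type A end-range
magnitudes and the anti-directional surplus of every record that crossed
upright. `max_demonstrated()` gives the per-level cohort maximum;
`frequency_stats()` the crossing frequencies and the type A rate as
"1 in N" (`N = round(total/count)`).

Output serialisation follows the reporting convention of the field:
flexion magnitudes negative, with an explicitly pro-normalised column kept
alongside to avoid downstream sign errors.

## Statistics

Type C vs type S end-ranges are compared per level with a two-sided
Mann–Whitney U test; groups with fewer than 7 records are *excluded*, not
tested (`status = "excluded-small-n"`), an explicit minimum-sample-size
rule rather than a silent small-sample test. The exact null distribution
is used when
n1+n2 ≤ 20 and there are no ties, otherwise the normal approximation with
tie and continuity corrections; each result records which was used, since
statistical packages differ in their defaults here. Direction comparisons
use Welch's t-test by default (pooled-variance behind a flag — the design
only specifies "independent-samples t-tests", and Welch is the safer
default under unequal variances). Normality is annotated via Shapiro–Wilk
and Lilliefors-corrected Kolmogorov–Smirnov tests, and never gates any
computation. No multiple-testing correction is applied; raw p-values are
reported.

## The synthetic generator

Real cervical fluoroscopy data cannot be redistributed, so validation runs
on synthetic cohorts whose defaults encode the emulated cohort design: 33
subjects × 7 joints × 2 directions, 16 s excursions at 25 fps with 2 s
holds, per-level end-range and surplus distributions parameterised from the
published per-level tables, type mixes from the published proportions, and
0.1° per-frame angle noise (sub-degree marking error). Three published
cells (flexion C1/C2 and C6/C7, extension C0/C1 end-ranges) were never
reported because of small group sizes; the generator's values for those
levels are synthetic stand-ins interpolated from whole-level averages and
neighbouring levels, and are documented as such.

Profiles are built from cubic smoothstep segments (`3t²−2t³`, C¹,
monotone between control points) with short plateaus centred exactly on
epoch boundaries: a type S joint rises to `end_range + surplus_pro`, holds
a plateau spanning the overshoot epoch's boundary, and descends to
`end_range`; an early dip plateau injects `surplus_anti` at the first
boundary; a type A joint rises to a small pro-directional peak (or not at
all, for the never-pro fraction) and terminates below upright. Because the
plateaus cover the boundary samples, the noise-free epoch-boundary
analysis recovers `end_range`, `surplus_pro` and `surplus_anti` *exactly*,
which is what makes 100% ground-truth recovery a meaningful test.
Magnitudes are drawn from one-sided truncated normals (end-ranges ≥ 0.3°,
surpluses ≥ 0.02°) — only means, SDs and ranges are published, and
truncation keeps every draw physical; it also biases means slightly above
the nominal parameter, which is visible in simulated surplus means.

`landmarks_from_angles()` inverts the geometry: it stacks a neutral
template (every midplane horizontal) and rotates each vertebra about its
own centroid, so recovered joint angles equal the requested ones to
machine precision; Gaussian coordinate jitter emulates marking error.

What the generator does *not* emulate: biomechanical coupling between
adjacent joints, out-of-plane motion, fluoroscopic distortion, or
subject-level correlation of joint behaviour. Passing recovery tests
therefore demonstrates correctness of the *pipeline arithmetic* under the
stated noise model, not robustness to every artefact of real fluoroscopy.

## Numerical and design choices

* Epoch boundary rounding: round-half-to-even; 1-based indices internally.
* The start sample counts as an attainable extreme, so `max_pro ≥ 0` and a
  type A joint always has `passed_endrange_pro` true.
* `end_range = 0` exactly → type C (strict A definition).
* Degenerate geometry (coincident reference points) and missing landmarks
  raise classed errors naming the vertebra, frame and landmark.
* Simulation seeding saves and restores the caller's RNG state.
* Problem sizes in the validation suite: ~2000-joint cohorts for
  classification recovery, 500 simulations for surplus recovery, 2000 null
  simulations for the rank-sum level, 10⁴ random walks for the
  decomposition identity — sizes at which the binomial/Monte-Carlo error of
  each check is far below its acceptance margin.

## Known limitations

* The pipeline assumes planar (sagittal) motion; out-of-plane rotation
  biases midplane angles and is not corrected.
* Published pass-frequencies for end-range/upright crossings do not
  exactly recompute from the published type counts (e.g. extension
  end-range passes print as 52.3% while (S+A)/231 gives 53.2%); the
  crossing rule here is the stated one (`max_pro > end_range`,
  `min_pos < 0`) and the discrepancy is documented rather than chased.
  Likewise the pooled type A proportion computes to 5.6% from the printed
  counts (26/462) although 5.7% was printed; the computed value is
  reported.
* Quartile aggregation uses the mean of per-joint percentages; the
  alternative reading (quartile mean surplus over quartile mean end-range)
  is a one-line change on the returned table and deliberately not a
  second code path.
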