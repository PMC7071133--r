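---
title: "Methods: markerless obstacle-crossing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: markerless obstacle-crossing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosteps)
```

## The problem

When people step over an obstacle, the two feet play different roles: the
*lead* foot crosses first, the *trail* foot follows without visual contact
with the obstacle. Depth sensors (RGB-D cameras of the Kinect v2 family)
allow markerless recording of such manoeuvres: the depth image is segmented
into a body point cloud, the per-foot clouds are extracted, and the
heel-to-toe *lower edge* of each foot — the profile of lowest points — is
tracked over time. From that lower edge this package computes the standard
crossing outcomes:

* **maximum step height** — the peak, over frames whose lowest edge point
  lies between 0.8 and 1.6 m along the walking path, of the per-frame
  minimum vertical value;
* **crossing height** — the minimum vertical position of any part of the
  foot while directly above a hurdle (front hurdle at 1.2 m; deep obstacles
  add a rear hurdle at 1.5 m);
* **foot clearance** — crossing height minus obstacle height; a negative
  clearance over a holographic obstacle is a virtual *collision* (for real
  obstacles the fallen bar is recorded instead);
* **mean forward velocity** — 1.7 m divided by the time the spine-shoulder
  point needs to travel from 0.1 to 1.8 m (crossing times found by linear
  interpolation).

Obstacles come in a 5 heights (0–0.4 m) by 2 depths (0.02, 0.30 m) grid and
are either physical or holographic (seen through a mixed-reality headset).
The scientific question downstream of the kinematics is whether an
individual's holographic-obstacle avoidance resembles their real-obstacle
avoidance; classical MDS over per-participant outcome vectors answers it,
and a feedback experiment tests whether deviating individuals adjust when
shown video of their own crossings.

## Synthetic cohorts and what they emulate

No recordings ship with the package; a generator produces the full study
design with planted ground truth so every stage is testable.

`design_cohort()` builds the complete factorial design: per participant two
obstacle-type blocks of 60 trials (5 heights x 2 depths x 6 repetitions),
obstacle-type order and depth order counterbalanced over participants, and
height-by-depth conditions block-randomised within each repetition round.
Twelve participants give 1440 trials. The default behaviour-mode layout for
a 12-participant cohort is 6 `similar`, 3 `extreme_lead` (participants 4,
7, 10) and 3 `no_trail_raise` (participants 1, 8, 11).

`simulate_trial()` produces a sensor-level trial: a 25-point skeleton
stream at 30 Hz and per-foot point clouds (a rigid sole polyline of 0.25 m
with 60 lower-edge samples plus instep points). The vertical swing is a
raised-cosine ramp up to a *flat plateau* whose height equals the planted
crossing height and which spans every hurdle by at least half a sole length.
This plateau construction is deliberate: because the sole is rigid and
pitched toe-up (heel lowest), every sole part passes each hurdle while the
foot centre is on the plateau, so the planted crossing height, the maximum
step height and the forward velocity are exact by construction rather than
by simulation accident, and noise-free pipeline runs must recover them to
machine precision. The price is realism: real swing trajectories peak once
and descend over the obstacle, real step height exceeds crossing height,
and real speed fluctuates within a trial. Passing recovery tests therefore
demonstrates correctness of the estimator chain, not robustness to every
curvature a real trajectory can show.

Default clearance draws are Gaussian per trial: lead N(0.13, 0.03) m and
trail N(0.15, 0.04) m, values in the range reported for young adults
crossing obstacles of comparable size. `extreme_lead` adds 0.25 m to the
lead clearance over holographic obstacles; `no_trail_raise` caps the trail
swing apex at 0.05 m (an unraised swing), which makes every 3D holographic
obstacle a virtual trail-foot collision. These are stated modelling
assumptions, configurable in `behavior_profile()`, not estimates from data
— per-participant clearance distributions are not published. Walking speed
defaults to 0.9 m/s with a mild decrease for higher and increase for deeper
obstacles, mirroring the qualitative condition effects.

Noise is applied after ground truth is fixed: isotropic Gaussian position
noise (default sd 5 mm, a realistic time-of-flight figure), per-frame
per-foot dropout (default 2%), and per-frame left/right label swaps
(default 2%) to exercise label correction.

The generator has a second, outcome-level entry point:
`simulate_cohort_outcomes()` returns the per-trial outcome table directly
from the planted parameters plus a small measurement error (default sd
3 mm, matching what the sensor-level chain delivers). Both levels share
`plant_trial_params()`, so for the same trial seed the planted values
agree exactly. Cohort-scale analyses (feature vectors, MDS, flags, ANOVA)
run on this fast path; the sensor-level path is exercised per trial
wherever the point-cloud pipeline itself is under test. A full
sensor-level cohort would add nothing to either kind of check.

## Pre-processing choices

* **Foot segmentation** is skeleton-guided: a body point belongs to a foot
  if it lies within 0.20 m of the segment from that side's ankle point to
  its foot-tip point, ties going to the nearer segment. The source data
  format (SDK skeletons plus depth) makes this the natural rule; the
  radius is configurable.
* **Lower edges** partition a foot cloud into 0.01 m along-path bins and
  keep the per-bin minimum vertical value. The bin width is finer than the
  30-part division it feeds, so binning never limits that algorithm.
* **Multi-sensor fusion** uses the primary sensor whenever the lower part
  of the foot is visible (at least 20 points within 0.10 m of the lowest
  point — the visibility criterion is our stand-in, as no threshold is
  published), otherwise substitutes the next sensor in priority, preferring
  the designated side sensor while the foot is inside the obstacle's
  occlusion window. Fusion never invents frames; every output frame's
  source is recorded.
* **Label correction** replaces manual inspection with centroid
  continuity: per frame, the left/right assignment minimising summed
  centroid displacement from the previous frame is kept; assignments
  within a 0.02 m deadband are marked unknown and the frame becomes
  missing (the automated analogue of "classified as missing"). When only
  one foot is visible it is relabelled to the nearer previous centroid —
  without this, a label swap coinciding with the other foot's dropout
  frame is uncorrectable and corrupts the crossing height.

## The crossing-height estimator

Per frame, the edge's x-extent is divided into 30 contiguous parts of
equal along-path length; a part's representative is (mean x, min z) of its
samples — the minimum is the conservative choice for clearance. Part
indices correspond across frames, so each part has a trajectory. A part
contributes when its representative brackets the hurdle position between
nearby frames, and the crossing height is the minimum over contributing
parts of the part's value at the hurdle.

Two numerical choices matter:

* **Gap limit.** With 1 cm bins and 30 parts over a ~0.25 m edge, a part
  can be empty in individual frames. Interpolating across arbitrary gaps
  can span the swing ramp and produce values far below the true crossing
  height, so bracketing pairs more than `max_gap = 3` frames apart are
  skipped; the affected part simply does not contribute (25+ parts
  remain).
* **Local fit.** The per-bin minimum of a handful of noisy points is
  biased low, and taking a minimum over ~25 parts compounds this to about
  −1 cm at 5 mm point noise. Each part's value at the hurdle is therefore
  estimated by a local least-squares line (linear in x) through the part's
  samples within ±5 cm of the hurdle whenever those samples straddle it;
  otherwise plain linear interpolation between the bracketing pair is
  used. Both estimators coincide exactly on noise-free locally-linear
  trajectories — which includes the generator's plateau — and the local
  fit averages enough frames to bring clearance recovery at 5 mm noise
  from ~93% to ~98–100% within ±1 cm.

Lead/trail roles are assigned by temporal order of the first hurdle-1
crossing of the foot centroid (first = lead). For maximum step height the
windowed test uses the x of the frame's arg-min point, the strictest
reading of "anywhere between 0.8 and 1.6 m".

## Dissimilarity screening

Each participant x obstacle-type object is a 250-element vector: for
hurdle 1, 5 heights x 2 depths x repetitions 2–6 x four outcomes (lead and
trail step height, lead and trail clearance), giving 200 elements; for
hurdle 2 (deep obstacles only), 5 heights x 5 repetitions x two clearances,
giving 50. Repetition 1 of each condition never enters any analysis (the
first-trial-effect exclusion); condition summaries are medians over the
available repetitions 2–6. The element ordering is fixed and documented
but inconsequential — any fixed ordering yields identical Euclidean
distances. Missing entries are imputed with the participant x condition x
outcome median and masked; distances over partially observed pairs use the
mutually available elements rescaled by sqrt(250/m), keeping them
comparable to fully observed pairs.

MDS is classical (Torgerson) scaling — double-centre the squared-distance
matrix, eigendecompose, scale eigenvectors by root eigenvalues —
deterministic up to reflections (signs are fixed by the largest loading).
The stress-majorisation alternatives add randomness without benefit at
this problem size; the choice is recorded in the embedding object via its
eigenvalue spectrum.

Subgroup flags operationalise what visual MDS inspection identified:

* `no_trail_raise`: trail-foot collision in at least 90% of analysed
  holographic 3D-obstacle trials;
* `extreme_lead`: the participant's mean holographic-minus-real lead
  step-height difference lies above the cohort upper 95% bound for at
  least 3 of the 4 3D heights.

For the second rule the bound for participant i is a *leave-one-out robust
prediction bound*, `median + t(0.975, m−1) · mad · sqrt(1 + 1/m)` over the
other participants' differences. A naive confidence interval of the cohort
mean would be exceeded by ~30% of perfectly ordinary participants (a CI of
the mean is not a band for individuals), and a non-robust spread estimate
would be inflated by the very participants the rule is meant to catch.
The robust leave-one-out bound flags planted extreme participants
essentially always and ordinary participants practically never, which is
the behaviour the screening requires.

## Feedback-block analysis

A feedback series has 30 trials: 2 familiarization, 5 baseline, 18
feedback, 5 follow-up; familiarization trials never enter intervals or
MDS. All intervals are t-based (`mean ± t(0.975, n−1) · sd/√n` — the
natural choice at n = 5), and two intervals *deviate* when they are
disjoint, an order-free and shift-invariant criterion. The
first-deviating-block statistic slides a window of five consecutive
feedback trials (window k covers trials 7+k…11+k, k = 1…14) and reports
the smallest k whose interval is disjoint from the baseline interval; the
feedback-block interval over all 18 trials is reported alongside, since
both summaries are informative. Simulated step adaptations at trial 8 with
effects of four baseline standard deviations or more are detected at
k = 1 in over 99% of runs, the pattern expected for participants who raise
their trail foot immediately after first seeing feedback.

The trial-level MDS builds one object per obstacle type and trial (3–30,
56 objects), with features concatenated over the subgroup's participants
(lead/trail clearance and step heights), and reports each holographic
trial's Euclidean distance to the mean feature vector of the 28 real
trials — the quantity that drops when an adaptation takes hold.

The generator's adaptation model: `no_trail_raise` applies a step change
of the trail crossing height at the onset trial (default 8, the first
feedback trial); `extreme_lead` decays the excess lead margin
exponentially with a time constant in trials (default 4); follow-up trials
retain a configurable fraction (default 0.8) of the adaptation reached by
trial 25.

## The inferential layer

The repeated-measures ANOVA is fully within-subject over crossed factors
(obstacle type x height x depth for hurdle-1 outcomes; obstacle type x
height for hurdle-2). Sums of squares come from the standard balanced
partitioning (base R `aov` with an `Error(subject/...)` term); the package
owns what `aov` does not provide: the balanced-design guard (participants
with any missing cell are dropped listwise, mirroring the exclusion of
non-adjusting participants from trail-foot analyses), Greenhouse–Geisser
and Huynh–Feldt epsilons computed from the orthonormally
contrast-transformed covariance (standard definitions, since no variant is
specified), the selection rule — Huynh–Feldt when the Greenhouse–Geisser
epsilon exceeds 0.75, Greenhouse–Geisser otherwise — and partial eta
squared, `SS_effect / (SS_effect + SS_error)`. Effects whose sum of
squares sits at floating-point rounding level are reported as F = 0,
p = 1, since `aov` otherwise returns an F near 1 built from rounding
noise. Normality screening is per-cell Shapiro–Wilk; post-hoc comparisons
are paired t-tests over all level pairs with Bonferroni multiplication
capped at 1.

## Problem sizes used by the test suite

The suite chooses sizes that make the statistical checks sharp while
keeping runs comfortable on a single core: 100 noise-free random-geometry
trials for oracle equivalence of the crossing height (tolerance 1e-3 m
against a dense-time brute-force re-simulation), 48 default-noise trials
(144 clearances) for parameter recovery, 100 random cohorts of 1440 trials
for subgroup-flag recovery, 1000 null replicates for the type-I-error
calibration of the 5-level within-factor test, 10,000 Gaussian blocks for
interval coverage, and 500 replicates for step-change detection.

## Known limitations

* The gait model is kinematic, not biomechanical: no joint dynamics, no
  balance, one swing per foot, no step-to-step variability in foot
  placement. Conclusions about estimator correctness transfer to real
  data; conclusions about robustness to gait pathology do not.
* The plateau swing makes maximum step height equal crossing height in
  synthetic trials, so tests cannot detect an estimator that confuses the
  two windows' extrema; the window logic is therefore tested separately on
  constructed edge series.
* Real-obstacle collisions rely on a bar-fall record; the generator
  equates it with negative planted clearance, which a physical bar need
  not obey (grazing contacts).
* The exclusion machinery (truncated recordings, unusable trails) is
  modelled only as explicit markers, not as a stochastic process.
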