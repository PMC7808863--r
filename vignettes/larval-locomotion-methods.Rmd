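---
title: "Quantifying larval locomotion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval locomotion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatrack)
```

## The assay

Baculovirus-infected caterpillars develop *enhanced locomotory activity*:
horizontal hyperactivity that precedes the climbing phase of the infection
and helps disperse the virus. To characterize it, a single larva is placed
in a 100 mm culture dish with a blob of artificial diet, over black paper,
and filmed for 24 h at one frame every 3 s; the frame is cropped to
520 x 400 px around the dish. `larvatrack` implements the complete analysis
of such recordings — position tracking, trajectory quality control,
behavioural quantification, spatial occupancy and group statistics — plus a
simulator that generates ground-truthed synthetic recordings so every stage
can be validated without original video.

## Tracking: background subtraction and centre of mass

Frames are converted to greyscale by an unweighted channel mean. The
background model is the *per-pixel average intensity over all frames*: a
larva that keeps moving occupies any one pixel for only a small fraction of
the record, so averaging recovers the empty scene, including every static
element (dish wall, diet blob). Each frame is then reduced to the absolute
difference from the background, thresholded, and 8-connected particles of
at least `min_area = 10` px are extracted; a particle's position is the
unweighted mean of its member pixel coordinates (the centre of mass of a
binarized particle). Coordinates are image-convention: `x` = column,
`y` = row, origin top-left, pixel centres at integers.

Two thresholding choices deserve comment:

* **Absolute vs signed difference.** The larva may be lighter or darker
  than its local background (over black paper vs over the pale diet blob),
  so the absolute difference is used.
* **Otsu with a floor.** The default threshold is Otsu's method on the
  256-bin histogram of the difference image. With a ~100 px larva in a
  208 000 px frame the foreground class is vanishingly small, and on
  low-contrast frames Otsu latches onto the sensor-noise distribution,
  returning thresholds of 1–3 grey levels that would mask half the image.
  The threshold is therefore floored at `min_fg_level = 10` grey levels:
  frames with no real foreground then produce (near-)empty masks whose
  stray noise pixels (about 0.25 per frame at `noise_sd = 2`) are removed
  by the `min_area` filter, while genuinely present but low-contrast larvae
  survive. A fixed threshold (`method = "fixed"`) is available when the
  recording conditions are known.

The background model has a structural failure mode: a larva that rests at
one spot for a substantial fraction of the record is averaged *into* the
background, leaving a ghost particle at the rest anchor and a fading true
particle. This is the regime in which nearly immobile control animals are
conventionally excluded from the assay; `qc_exclusion_flag()` provides a
reproducible proxy (exclude when more than 20 % of frames lack a genuine
detection). The manual validity check this replaces has no published
criterion, so the 20 % cut-off is this package's choice, exposed as a
parameter.

## Trajectory quality control

Three rules convert raw detections into exactly one position per frame:

1. detections farther than `dish_radius + 2` px from the dish centre are
   physically impossible and removed;
2. several detections in one frame (a larva split by binarization) are
   replaced by the unweighted average of their coordinates;
3. a frame with no detection takes the position of the most recent earlier
   frame (carry-forward). Frames before the first detection back-fill from
   it rather than being dropped — the 24 h frame grid must stay intact for
   the 30 s windowing — and are flagged `back_filled` in the provenance
   column.

A consequence of carry-forward worth knowing: the interval that ends at a
carried frame has distance 0 and the following interval absorbs the
accumulated jump. No smoothing or filtering is applied; positions are raw
centroids.

## Behavioural quantification

Per-interval displacements (Euclidean, pixels per 3 s) are classified as
*movement* when they strictly exceed 0.5 px, else *stationary*. Whether a
displacement of exactly 0.5 px counts as movement is not fixed by the
verbal rule "exceeded 0.5 pixels"; the strict reading is adopted and the
threshold is a parameter. The interval series is then averaged over
consecutive non-overlapping 30 s windows (10 intervals) anchored at the
first interval — the simplest reproducible alignment, since nothing in the
verbal definition fixes one — and a window whose mean exceeds the same
0.5 px threshold counts as "kept moving". A maximal run of qualifying
windows is one *continuous locomotion* event (bout). A trailing partial
window is averaged over its actual members and flagged rather than
discarded. Four per-larva metrics summarize the record:

| metric | definition | units |
|---|---|---|
| total distance | sum of all inter-frame displacements | px / 24 h |
| locomotory speed | median displacement over moving intervals | px per 3 s interval |
| locomotory duration | median bout length | 30 s windows |
| locomotory frequency | number of bouts | events / 24 h |

Speed is reported in px per interval (the native resolution; a px/s column
is added for convenience). When a larva never moves, speed and duration are
reported as missing, not zero.

## Spatial occupancy

The 24 h record is divided into eight 3 h segments (remainder frames, if
any, join the last segment) and each segment's position cloud is summarized
by: the median radial distance from the dish centre as a fraction of the
dish radius; the fraction of positions within `food_radius + 10` px of the
diet blob; and the fraction beyond 0.8 of the dish radius ("edge").
The 0.8 cut-off and 10 px food margin quantify the qualitative contrast
between food-centred and edge-following occupancy; both are parameters.
`export_distribution_plot()` draws the per-segment scatter panels and emits
the plotted points as CSV so figures are verifiable.

## Group comparison

Metrics are compared between mock- and virus-infected groups with a
two-sided Wilcoxon–Mann–Whitney rank-sum test using mid-ranks for ties.
For combined samples up to 16 animals — which covers the design of six per
group — the p-value is computed by complete enumeration of all
`choose(n1 + n2, n1)` assignments of the observed ranks, exact with or
without ties; larger samples use the tie-corrected normal approximation
with continuity correction. Results are reported per experiment and pooled
(the published design plots experiments separately but does not state how
they were tested; both are given, labelled). No multiple-testing correction
is applied, matching the assay's convention; this is noted in the output
documentation.

## The synthetic larva

`simulate_trajectory()` draws from a two-state semi-Markov model chosen as
the simplest family in which bout *frequency*, bout *duration* and
*speed* are independently controllable — the three properties the assay
separates:

* stationary phase durations are exponential with rate `bout_rate_per_h`
  (default 2/h, giving ~45 bouts per 24 h);
* bout durations are gamma (`shape = 2`, mean 120 s for the mock regime);
* per-interval steps during a bout are lognormal with mean `step_mean_px`
  (mock 2 px per 3 s) and `sdlog = 0.5`;
* headings follow a correlated random walk: normal turn angles with
  standard deviation `pi * (1 - heading_persistence)`, default
  persistence 0.7;
* stationary phases jitter uniformly in a 0.15 px disc about their anchor
  (net step at most 0.3 px), so the 0.5 px classifier is exercised near its
  boundary, as real centroids fluctuate.

Spatial behaviour comes in two modes. Food-centred larvae drift back
toward the diet blob and reflect specularly off the dish wall;
edge-following larvae drift outward and travel tangentially along the
wall, reproducing wall-hugging scatter. The infected default
(`infected_params()`) doubles step mean and bout duration at an unchanged
bout rate and switches from food-centred to edge-following 9 h into the
record, encoding the infection phenotype: faster, longer locomotion at
unchanged frequency, with late-stage dysregulation of the spatial pattern.
Because published outcomes for this assay are box plots without printed
values, the parameter magnitudes are calibration choices fixed once, not
measured quantities; the *ratios* (×2 speed, ×2 duration, ×1 rate) are the
modelled effect.

`render_frames()` rasterizes a trajectory into 8-bit frames: an
anti-aliased ellipse (half-axes 6 × 3 px) oriented along the heading, over
a uniform 30 grey-level background with a 90 grey-level diet blob, larva at
140, Gaussian pixel noise (`noise_sd = 2` default), optional per-frame
dropout (exercises gap filling) and clutter blobs (exercise
multi-detection averaging). Cohorts use per-larva seeds derived from a
master seed by a splittable counter (`child_seed()`), so any subset of a
cohort is reproducible in isolation.

What the generator does *not* emulate: body posture and peristalsis (the
larva is a rigid blob), partial occlusion by the diet, illumination drift,
shadows, and moulting or death during the record. Passing the synthetic
acceptance checks therefore validates the algorithmic chain, not robustness
to those real-world artefacts.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
particle detection against a brute-force flood fill (exhaustively on all
65 536 4x4 masks and on random 64x64 masks), the Otsu threshold against
direct maximization of between-class variance, bout segmentation against a
scan-based run-length oracle (1 000 random patterns), and the exact
rank-sum p against full bitmask enumeration of assignments. End-to-end,
tracking a noisy 500-frame render of a continuously moving larva recovers
the trajectory to ~0.2 px RMS (the 1 px acceptance bound); recovery of the
×2 speed/duration effects uses 20 replicate cohorts of 6 + 6 larvae at
24 h, and the joint significance pattern (distance, speed, duration
significant at 0.05; frequency not) is checked over 50 replicate cohorts
of 10 + 10. Null calibration of the exact test uses 1 000 simulated
6 + 6 datasets, with the rejection rate at nominal 0.05 required to fall
in [0.02, 0.08].

## Known limitations

* Background-subtraction tracking degrades for animals that rest long at
  one anchor (ghost particles); the exclusion flag detects, not repairs,
  this.
* Multi-detection *averaging* is the published rule, but with a clutter
  blob present it pulls the position toward the clutter; no identity
  tracking is attempted (one animal per arena is assumed).
* The windowed bout definition merges bouts separated by less than one
  window and can split or shave bouts at window boundaries; recovered bout
  counts are therefore biased slightly relative to the generator's event
  count (the tests band this at roughly ±30 %).
* Only horizontal locomotion is modelled; no vertical (climbing) axis.
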