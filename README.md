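# larvatrack

Quantitative analysis of single-larva locomotion in dish arenas from
time-lapse recordings, for researchers studying insect behaviour and its
manipulation by parasites — in particular the *enhanced locomotory
activity* (hyperactivity) that baculoviruses induce in lepidopteran larvae
before the climbing phase of infection.

A larva in a 100 mm culture dish (with a blob of artificial diet) is
filmed for 24 h at one frame per 3 s. `larvatrack` turns such recordings
into per-larva behavioural metrics and group comparisons:

1. **Tracking** — greyscale conversion, background model
   \(B(p) = \frac{1}{T}\sum_t I_t(p)\) (per-pixel average intensity),
   thresholding of \(|I_t - B|\) (Otsu with a noise floor, or fixed), and
   8-connected particle detection with unweighted centroids.
2. **Trajectory QC** — removal of out-of-dish points, averaging of
   multiple detections per frame, carry-forward filling of missing frames,
   and an exclusion flag for animals whose background model failed.
3. **Locomotion metrics** — an interval moves when its displacement
   \(d_i > 0.5\) px; 30 s windows whose mean displacement exceeds 0.5 px
   form maximal runs ("continuous locomotion" bouts). Per larva:
   total distance \(\sum_i d_i\), median moving speed
   \(\mathrm{med}\{d_i : d_i > 0.5\}\), median bout duration (in 30 s
   windows) and bout count.
4. **Spatial occupancy** — eight 3 h segments with median radial fraction,
   food fraction and edge fraction (r/R > 0.8), plus scatter panels.
5. **Statistics** — exact Wilcoxon–Mann–Whitney rank-sum tests (complete
   enumeration, mid-ranks for ties) per metric, per experiment and pooled.

Because the original videos of such assays are rarely released, the
package includes a ground-truthed simulator: a two-state semi-Markov larva
(exponential stationary phases, gamma movement bouts, lognormal steps on a
correlated random walk, food-centred or edge-following drift) and a frame
renderer with noise, dropout and clutter. Every pipeline stage is
validated against this ground truth and against brute-force oracles.

## Worked example

Simulate a two-group cohort under the default regimes (infected larvae:
doubled step length and bout duration, unchanged bout rate, edge-following
from 9 h) and compare the groups:

```r
library(larvatrack)
arena <- arena_spec()     # 520 x 400 px crop, dish r = 190 px, 3 s/frame

coh <- make_cohort(arena, mock_params(), infected_params(),
                   n_per_group = 6, seed = 1, duration_h = 24)
metrics <- cohort_metrics(coh, experiment = "1")
aggregate(cbind(total_distance_px, median_speed_px_per_interval,
                median_bout_duration_windows, bout_count) ~ group,
          metrics, median)
#>      group total_distance_px median_speed_px_per_interval
#> 1 infected          18268.61                     3.518988
#> 2     mock           7409.23                     1.762770
#>   median_bout_duration_windows bout_count
#> 1                          8.5       48.5
#> 2                          4.0       46.5

compare_groups(metrics)[, c("metric", "U", "p_two_sided", "sig_0.05")]
#>                         metric    U p_two_sided sig_0.05
#> 1            total_distance_px 36.0 0.002164502     TRUE
#> 2 median_speed_px_per_interval 36.0 0.002164502     TRUE
#> 3 median_bout_duration_windows 36.0 0.002164502     TRUE
#> 4                   bout_count 17.5 0.948051948    FALSE
```

Infected larvae travel ~2.5× farther, move ~2× faster per interval and
~2× longer per bout (all significant by exact rank-sum test at n = 6 + 6),
while bout *frequency* does not differ — the signature that infection
manipulates speed and duration but not the rhythm that initiates
locomotion. The spatial signature appears in segmented occupancy:

```r
occupancy_by_segment(coh[[7]]$truth$positions, arena)[c(1, 8), ]
#>   segment median_radial_fraction food_fraction edge_fraction n_positions
#> 1       1              0.1438273     0.8994444             0        3600
#> 8       8              0.9552310     0.0000000             1        3601
```

— food-centred early (segment 1), wall-hugging late (segment 8).

To analyse real recordings, start from `read_frames()` (PNG directory or
multi-page TIFF) → `track_stack()` → `clean_detections()` →
`locomotion_metrics()`; a thin command-line wrapper for each step is in
`inst/cli/larvatrack.R`, configured by a YAML file (see
`inst/extdata/example_config.yaml`).

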