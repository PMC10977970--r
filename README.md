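# gridtask

Classification of grid-cell firing on a virtual linear track as
**task-anchored**, **task-independent** or **aperiodic**, with the
behavioural scoring and spike-train simulation needed to validate the
classifier end to end.

## The problem

Grid cells of the medial entorhinal cortex fire periodically in space. On a
repeating 200 cm virtual track a grid cell can *anchor* its fields to the
track, reproducing the same firing positions every trial, or keep firing at
a fixed travelled distance so its fields drift through the track reference
frame — or lose periodic structure altogether. Anchoring is the regime in
which a grid code can support path integration towards a learned reward
zone, so knowing which mode a cell is in, trial by trial, is what lets one
ask whether grid anchoring predicts successful behaviour on trials without
a visual cue.

## The method

For each cell the package builds trial-wise firing rate maps (1 cm bins,
Gaussian smoothing SD 2 cm) and computes Lomb-Scargle periodograms of the
rate signal as a function of cumulative distance: 600 cm windows every
10 cm, with distance in units of the track length, so spatial frequency *f*
counts oscillations per trial (capped at 5). Power uses the floating-mean
least-squares spectrum with standard normalisation — the variance fraction
explained by a sinusoid at *f*, bounded in [0, 1].

Averaged periodogram peaks are compared against a **field-shuffle false
alarm threshold**: firing fields are segmented from the unsmoothed map
(SD 4 cm smoothing, 20 cm minimum peak distance, fields between adjacent
troughs) and relocated to random positions 1000 times; the threshold is the
99th percentile of surrogate peak powers. A cell above threshold is

* **TA** (task-anchored) if |peak frequency − nearest positive integer| ≤ 0.05,
* **TI** (task-independent) otherwise,
* **aperiodic** if below threshold.

Rolling windows of 200 periodograms (10 trials) give trial-level labels via
a midpoint rule and per-trial majority vote. Around the classifier sit:
spatial information (Σᵢ Pᵢ λᵢ log₂(λᵢ/λ), bits/s), open-arena grid-cell
identification (grid score and half-session stability vs 1000 time-shift
shuffles), pairwise coding agreement with splice shuffles, a common
population label, hit/try/run behavioural scoring (stop = speed < 4.7 cm/s
in the 60–80 cm reward zone), stop-density profiles with uniform-shuffle
baselines, a template-matching trial classifier, and a simulator producing
grid/place/ramp/shuffled-field/noise cells with known per-trial ground
truth.

## Worked example

Simulate a 40-trial session in which a grid cell (spacing 70 cm) alternates
between anchored and independent firing in blocks, then classify it at
trial resolution (simulated data skip the field shuffle, forcing the
two-way TA/TI decision):

```r
library(gridtask)
cfg <- sim_config(grid_spacing_cm = 70, mode = "alternating_blocks",
                  n_trials = 40, seed = 3)
ses <- simulate_session(cfg)
g <- classify_grid_code(ses$spikes$cell1, ses$positions, mode = "rolling",
                        use_field_shuffle = FALSE, seed = 3)
print(g)
#> Spatial code classification (rolling mode)
#>   trials: 40, spikes: 20803
#>   session label: TA  (peak 2.970 osc/trial, power 0.574)
#>   trial labels: TA 30, TI 10
mean(g$raster$label == ses$truth$cell1) * 100
#> [1] 72.5
```

The session-average periodogram peaks at 2.970 oscillations/trial — within
the 0.05 tolerance of the integer 3 (the track holds about three 70 cm
fields), so the session as a whole reads task-anchored; the rolling window
recovers the cell's TI epochs on 10 of 40 trials, and 72.5% of trial labels
match the simulator's ground truth (labels lag true switches by up to half
a 10-trial window). `summary()` adds rates and spatial information;
`plot()` draws the rate map, the averaged periodogram and the label raster.

The validation harness reproduces the accuracy/bias sweeps on simulated
populations:

```r
cell_level_eval(n_ta = 50, n_ti = 50, tolerances = 0.05, seed = 1)
#>   tolerance p_max jitter_sd accuracy_pct bias_pct n_cells
#> 1      0.05   0.1         0           99       -1     100
```

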