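---
title: "Classifying task-anchored and task-independent grid firing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying task-anchored and task-independent grid firing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grid cells in the medial entorhinal cortex fire in periodic spatial patterns.
When an animal runs repeated trials on a virtual linear track, a grid cell can
behave in two qualitatively different ways: it can anchor its firing fields to
the track, so the same positions are active on every trial (*task-anchored*,
TA), or it can keep firing at a fixed travelled distance regardless of where
the track repeats (*task-independent*, TI). A third possibility is that the
periodic structure disappears altogether (*aperiodic*). Distinguishing these
modes matters because anchoring to the task reference frame is the regime in
which a grid code can support path integration towards a learned goal: on
trials where the reward location is not visually cued, the animal must
estimate its position from self-motion alone.

`gridtask` implements the full analysis chain for this question: trial-wise
firing rate maps, spatial periodograms in the distance domain, a
field-shuffle null distribution, classification at session, rolling-window
and single-trial resolution, agreement statistics across simultaneously
recorded cells, behavioural scoring of stopping, a template-matching
alternative classifier, and a spike-train simulator with known ground truth
used to validate every stage.

## The classifier

The firing rate map of a cell is built on 1 cm bins for each trial of the
200 cm track (spike counts divided by dwell time, Gaussian-smoothed with
SD 2 cm). Concatenating trials gives firing rate as a function of cumulative
distance. Lomb-Scargle periodograms are computed over 600 cm windows (three
track lengths) every 10 cm. Distance is expressed in units of the track
length, so a spatial frequency *f* counts oscillations per trial: a cell
anchored to the repeating track has its periodogram peak at a positive
integer, while a distance-periodic cell with spacing λ peaks at 200/λ,
integer only by coincidence.

The periodogram is the generalized (floating-mean) least-squares spectrum
with the standard normalisation: at frequency *f* the power is the fraction
of the signal variance explained by the best-fitting sinusoid `a + b cos(2πf
x) + c sin(2πf x)`, so power lies in [0, 1] and is invariant to rescaling the
rates. Because rate signals are sampled on a uniform 1 cm grid, the sinusoid
design matrix is identical for every window; the implementation evaluates
all windows against one precomputed basis with two matrix products, which is
what makes shuffle-based thresholds affordable.

Windowed periodograms are averaged — over the whole session for a session
label, or over a rolling window of 200 periodograms (10 trials) for
trial-level labels. The peak of the averaged periodogram is compared with a
false alarm threshold (below); peaks above it are classified TA when the
distance between the peak frequency and the nearest positive integer is at
most 0.05, and TI otherwise. For peak frequencies below 0.5 the nearest
positive integer is 1, so the distance is 1 − *f*.

Rolling windows are mapped to trials by the midpoint rule: each window is
assigned to the trial number nearest its midpoint in trial units (a midpoint
of 10.4 belongs to trial 10; 10.6, and the border case 10.5, to trial 11),
and each trial takes the majority label of its windows.

### The field-shuffle null

The false alarm threshold asks how large a periodogram peak could be if the
cell's firing fields were placed without periodic structure. Fields are
segmented once from the unsmoothed rate signal: the signal is smoothed with
a wider Gaussian (SD 4 cm), peaks and troughs are detected with a 20 cm
minimum separation, and a field is the inter-trough region containing a
peak. Each surrogate relocates the fields to random non-overlapping
positions (random field order, uniform gap placement), with the non-field
bins filling the remaining gaps in their original order — a permutation of
the bin values that preserves local field structure while destroying
periodic placement. Surrogates are smoothed (SD 2 cm) and their periodograms
computed exactly as for the data; the threshold is the 99th percentile of
1000 surrogate peak powers. Because averaging more windows shrinks noise
peaks, the rolling classification uses an *adjusted* threshold built from
each surrogate's first 200 periodograms rather than single windows.

For simulated data the field shuffle is skipped and no threshold applied,
forcing a two-way TA/TI decision; silent or constant cells are labelled
aperiodic by convention.

## The simulator

Synthetic sessions emulate an agent running at a constant 10 cm/s over 100
trials of a 200 cm track (60 cm track zone, 20 cm reward zone at 60–80 cm,
60 cm track zone, 60 cm black box), sampled at 1000 Hz, with trial types
cycling a repeating block pattern (default `BBN`: beaconed, beaconed,
non-beaconed). Firing is generated from a probability density function over
position with range 0–1, scaled by `p_max_spike` (default 0.1) and sampled
as an independent Bernoulli event per position sample:

* **anchored grid** — Gaussian kernels (SD = 0.1 λ) at identical track
  positions every trial;
* **independent grid** — the same kernels continued across trial boundaries
  at spacing λ in cumulative distance, so the within-track phase advances by
  `200 mod λ` per trial;
* **place** — one kernel (mean 100 cm, SD 10 cm) repeated every trial;
* **ramp** — linear ramp from 0 at the track start to the maximum at 200 cm;
* **shuffled field** — the place PDF passed through the field shuffle;
* **noise** — uniform.

Alternating cells merge the anchored and independent PDFs either in blocks
(first trial by fair coin, then a 10% per-trial switch probability) or by an
independent fair coin every trial, and carry their true per-trial labels.

Stopping behaviour is generated by an explicit policy (per-visited-cm stop
probabilities, optionally elevated in the reward zone and optionally only on
a chosen set of trials) overlaid on the kinematic trace as a synthetic speed
channel: baseline 40 cm/s with Gaussian noise (SD 5 cm/s), interrupted by
~0.5 s dwells below the 4.7 cm/s stop threshold. This generator is an
extension beyond the spike simulator — the experiments it stands in for
recorded real mice — and exists so the behavioural scoring (hit/try/run,
stop densities, label-conditioned comparisons) can be tested end to end with
known selectivity.

What the simulator does *not* emulate: variable running speed coupled to
position, teleportation gaps, licking and reward delivery, theta modulation,
bursting or refractoriness, electrode drift, or noise correlations between
cells. Passing tests on synthetic data therefore demonstrate that the
implementation recovers the constructs it defines — not that classification
of real recordings is error-free; in real data occupancy is non-uniform and
firing non-Poisson, which the shuffle-based thresholds absorb only in part.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| rate-map bin | 1 | cm | spatial resolution of all 1D analyses |
| rate-map smoothing SD | 2 | cm | de-noising before spectral analysis |
| window length | 600 | cm | periodogram sample length (3 trials) |
| window step | 10 | cm | 20 periodograms per trial |
| frequency cap | 5 | osc/trial | spacings below 40 cm do not occur |
| frequency tolerance | 0.05 | osc/trial | TA vs TI decision margin |
| rolling window | 200 | periodograms | 10 trials; accuracy/bias optimum |
| shuffles | 1000 | — | 99th-percentile false alarm threshold |
| field-detection SD / min distance | 4 / 20 | cm | field segmentation |
| stop threshold | 4.7 | cm/s | definition of a stop |
| unclassified cut | 10 | cm/s | mean out-of-zone speed floor |
| reward zone | 60–80 | cm | hit definition |
| arena bin / shift range | 2.5 cm / 20–580 s | — | open-arena grid calls |

## Numerical and design choices

Where the procedure leaves details open, the package fixes them as follows.

* **Frequency grid** 0.05–5.0 in steps of 0.01 oscillations/trial; the step
  is far below the 0.05 tolerance, and the grid contains the integers, so a
  noiseless anchored cell scores an integer peak exactly.
* **Peak** of a periodogram is its global maximum; plateau ties resolve to
  the lower frequency. Windows are dropped (not padded) at the session tail;
  no taper is applied.
* **Smoothing** uses reflective padding, which preserves per-trial mean
  rate; Gaussian kernels are truncated at ±4 SD. `NA` bins (zero occupancy)
  are excluded with kernel renormalisation rather than treated as zero rate.
* **Field segmentation is reused** across a cell's 1000 surrogates
  (placement, not detection, is randomised), and the surrogate generator
  places reordered fields with uniform random gaps.
* **Independent-mode phase origin** is λ/2 in cumulative distance, and
  jitter displaces fields in cumulative-distance coordinates; any fixed
  origin is equivalent for the statistics computed. One jitter value is
  drawn per field instance.
* **Majority votes** (trial assignment, common label) break exact ties in
  the fixed order TA, TI, aperiodic; trials with no rolling window (the
  first and last ~3 trials) inherit the nearest labelled trial's label and
  are flagged. Trials where both cells are aperiodic count as agreeing.
* **Two-cell populations** without perfect agreement are represented by one
  randomly selected cell (seeded); the epoch block-length null permutes
  trial labels; the splice shuffle reorders maximal same-label runs and the
  shuffled agreement is reported as the mean over 10 shuffles applied to the
  second cell of the pair (agreement is symmetric, so the choice is
  cosmetic).
* **Try/run split** compares per-trial *mean* reward-zone speed with the
  95th percentile of the hit trials' means; the unclassified rule is applied
  first; a contiguous sub-threshold interval is one stop at its onset. The
  black box (140–200 cm) is included in "outside the reward zone" by
  default (configurable).
* **Template classifier** uses the plain mean over TA trials (no
  leave-one-out) over all 200 bins including the black box, excluding
  unvisited bins pairwise; units under 15% TA trials are discarded.
* **Open arena**: autocorrelograms require at least 20 overlapping visited
  bins per lag; local maxima of the binarised (20% of maximum)
  autocorrelogram are 8-connected components; a grid score needs more than
  seven of them; sessions shorter than 600 s shrink the spike-time shift
  range to [20 s, duration − 20 s].
* **Seeding**: one session seed fans out to named per-component streams, so
  adding a cell never perturbs another cell's draws.

## Problem sizes used in the tests

The validation harness mirrors the published sweeps at desk scale: 50 + 50
cells (rather than 500 + 500) for cell-level accuracy and bias, 100
field-shuffle surrogates (rather than 1000) where a threshold is exercised
in a test, and sessions of 10–100 trials depending on what a test needs.
These sizes were chosen once as the smallest at which the statistics of
interest are stable; the full-scale settings remain available through the
ordinary function arguments (`n_ta`, `n_ti`, `n_shuffles`).

## Known limitations

* Classification at trial resolution is limited by the 10-trial rolling
  window: labels lag genuine switches by up to half a window, and frequent
  alternation (every trial) cannot be tracked — this is a property of the
  method, reproduced faithfully.
* A task-independent cell whose spacing divides 200 cm within the tolerance
  (e.g. λ ≈ 200/k) is indistinguishable from an anchored cell in the
  periodogram; such cells bound the attainable accuracy of any classifier
  built on peak frequency.
* The Lomb-Scargle power assumes an additive sinusoid model; strongly
  skewed firing profiles spread power into harmonics, which the integer
  rule tolerates for anchored cells but which can depress TI peak heights.
* The behaviour generator is phenomenological; its speed channel is not
  coupled back into the kinematics (positions remain constant-speed), so
  occupancy-dependent artefacts of real stopping are not reproduced.
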