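---
title: "Quantifying endosome dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endosome dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`endotrack` re-implements, as a tested pipeline, the quantitative live-cell
imaging analysis used to characterize how septin-decorated actin filaments
control the dynamics of AP-3-coated early endosomes: coated objects are
immobile while bound to filaments, detach and move short distances at a
characteristic directed speed (about 1 µm/s), and associate with
EGF-containing compartments for about a minute in control cells but only
briefly (20–30 s) when septins are depleted. This vignette explains the
models behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the design decisions taken where
the original description was open.

## The measurement chain

Analysis of a two-channel time-lapse acquisition proceeds through five
stages, each exposed as package functions:

1. **Bleach correction** (`bleach_correct`): every frame is rescaled
   multiplicatively so its mean equals a reference level (first frame by
   default). This is intensity normalization, not a photophysical model; it
   restores the *background-dominated* frame mean exactly and is sufficient
   for stable thresholding downstream.
2. **Spot detection** (`detect_spots`, `detect_movie`): the undecimated
   à-trous wavelet transform with the separable B3-spline kernel
   (1,4,6,4,1)/16 and mirror boundaries decomposes each frame into detail
   planes that sum back to the input exactly. Detail planes 2 and 3 are
   thresholded at `k_mad = 3` times a robust noise estimate
   (1.4826 × median absolute deviation, insensitive to the spots
   themselves); the conjunction of the masks is segmented into components of
   at least 2 px. Sub-pixel positions are intensity-weighted centroids over
   the background-free reconstruction (the summed detail planes), matching a
   criterion phrased in terms of centroid resolution rather than PSF-fit
   precision.
3. **Linking** (`link_frames`, `build_tracks`, `filter_tracks`): detections
   in consecutive frames are matched by a globally optimal one-to-one
   assignment under the cost
   `w_dist · d/gate + w_int · |ΔI|/intensity_scale`, with pairs beyond the
   5 px gate forbidden and unmatched detections (birth/death) charged
   `w_dist + w_int` each. The solver is a Jonker–Volgenant-style shortest
   augmenting path method on the standard augmented matrix; tests verify its
   optimality against brute-force enumeration. There is no gap closing: the
   published filter demands *consecutive* frames, so a missed detection ends
   a track. Tracks with fewer than 6 detections (i.e. not "more than 5
   consecutive frames") are discarded.
4. **Motility** (`classify_steps`, `track_metrics`): a step is immobile when
   its Euclidean displacement is strictly below 3 px — the centroid
   resolution criterion — and motile otherwise. At the trajectory
   acquisition calibration (143 nm pixels, 475 ms between frames) a 1 µm/s
   object moves 3.3 px/frame and classifies motile; at the 154 ms interval
   the same object moves 1.1 px/frame and is below the criterion, which is
   why speed recovery is only meaningful in the 475 ms regime. Mean motile
   speed averages motile steps only; immobile steps reflect localization
   jitter, not transport, and a track with no motile step reports `NA`,
   never 0. The overall step speed is reported alongside.
5. **Association** (`object_coloc_fraction`, `coloc_time_course`,
   `association_runs`, `dwell_stats`): colocalization is object-based — the
   fraction of channel-A centroids within a radius (3 px, the same spatial
   scale as the motility criterion) of a channel-B centroid; the measure is
   directional and both directions should be reported. Association runs use
   a sticky assignment (the current reference is kept while it stays within
   the radius) and, with `max_gap_frames = 0`, a single out-of-radius frame
   ends a run. Runs touching a track boundary are censored: their duration
   is only bounded below, and they are excluded from dwell means by default.

Replicate aggregation (`aggregate_conditions`, sample SD with the n−1
denominator) and per-time-point single-factor ANOVA
(`anova_single_factor`, the classical F = MS~between~/MS~within~) mirror the
spreadsheet-based statistics of the original workflow; no multiple-testing
correction is applied across time points, and the output records that.

## The synthetic generator

No imaging data accompanied the study, so every stage is validated against
a generator (`sim_config`, `simulate_movie`) whose defaults encode the
acquisition constants: 600-frame series, 143 nm pixels, 154 ms frame
interval (475 ms in the trajectory presets), and a two-state motion model.

**Motion.** Objects alternate exponential bound sojourns (mean
`bound_dwell_s`; 60 s in the control preset, 25 s in the depleted preset,
inside the reported 20–30 s range) with motile excursions (directed motion
at `motile_speed_um_s = 1`, heading diffusing with per-frame sd 0.2 rad).
State switching is continuous-time; positions are sampled on the frame
grid; boundaries reflect so the object count is constant. Excursions are
short — `free_dwell_s = 5` s (≈5 µm of travel) in the control preset — which
is the regime described qualitatively as detaching and "moving over short
distances" before rebinding; the depleted preset doubles the excursion time,
reproducing longer tracks at the same speed.

**Binding and docking.** An excursion ends in one of two ways. With a
probability calibrated to the target colocalized fraction, the object is
transported in a straight line at its motile speed to a dedicated reference
compartment (an endosome analogue rendered in the second channel) and docks
there; otherwise it keeps wandering until it encounters a filament within a
1.5 px capture radius and rebinds. Three choices here deserve comment:

* *No teleports.* An earlier design anchored objects to the nearest
  filament point at the moment of binding, which jumps the object several
  pixels within one frame. Such jumps exceed the linking gate, so the
  generator itself would break every track at every binding event. Binding
  by encounter keeps trajectories continuous and linkable.
* *Dedicated compartments.* Each object docks only on its own reference
  compartment, and rebinding avoids compartment neighbourhoods and occupied
  filament sites. This guarantees two spots never co-localize persistently
  within the PSF (which no detector can separate) and makes the docked
  dwell measurable. Biologically it encodes directed transport of a coat to
  its target compartment and one coat per docking site.
* *Fly-by suppression.* A motile object crossing the 3 px association disk
  of a compartment creates a genuine but sub-second association run. Under
  a design where compartments sit at arbitrary binding anchors, such
  fly-bys outnumber real dockings roughly two to one and drag the mean
  association run far below the bound dwell; with docking, short
  excursions, and rebinding kept away from compartments, fly-bys are under
  ten percent of events.

**Image formation.** Objects render as 2-D Gaussians (vesicle channel:
σ = 1.3 px, peak 500 counts; reference channel: σ = 2.5 px, peak 200 counts
— larger, dimmer structures) on a 100-count background. The whole frame
bleaches as exp(−t/τ) with τ = 600 frames, so the end of a default series
retains 37% of its signal; Poisson shot noise and Gaussian read noise
(sd 2) follow, quantized to 16-bit counts. Peak signal-to-noise at frame 0
is ≈50:1 — a bright, well-sampled TIRF-like regime. The original
acquisitions' SNR and localization precision were not reported, so these
are generator defaults stated here, not inferred values.

**What the generator does not emulate.** No filament dynamics, no 3-D
defocus, no merging or splitting of compartments, no cargo chemistry, no
camera gain calibration, no motion blur within an exposure. Passing the
recovery tests therefore demonstrates the pipeline's correctness under the
stated image-formation and motion model, not robustness to every real-data
pathology (uneven illumination, focus drift, vesicle fusion).

## Numerical and statistical choices

* **Watershed splitting of touching spots.** Two objects 3–5 px apart merge
  into one thresholded component; the detector splits components at
  intensity watershed lines with a tolerance equal to the detection
  threshold (`k_mad` times the combined plane noise), so noise bumps on a
  single spot do not fragment it. This resolves pairs down to roughly 2σ of
  the PSF and is the one place the implementation refines the plain
  connected-components construction.
* **Dwell estimation needs long windows.** The mean of *completed*
  exponential intervals observed in a window of length T underestimates the
  true mean μ unless T ≫ μ: only intervals shorter than the remaining
  window complete. Analytically the bias stays within 5% only for
  T ≳ 20 μ. Track breaks shorten the effective window further. The
  dwell-recovery experiment (`dwell_recovery_experiment`) therefore uses
  3000-frame series at 475 ms (≈24 μ) with 4 objects per field (collisions
  that fragment tracks become rare) and a bleaching constant scaled to the
  series length (a longer acquisition at the default τ = 600 would lose all
  signal; a real experiment would lower excitation accordingly). With this
  design the pipeline recovers a configured 60 s dwell to within about ten
  percent (the residual shortfall is track-level truncation plus the small
  fly-by share); at the default 600-frame length the same estimator reads
  ≈20 s low — a truncation artefact users should expect on short series.
* **Colocalization sampling error.** Within one acquisition the
  within-radius indicator is autocorrelated over the dwell time, so a
  single movie's colocalized fraction scatters several percent around the
  configured value even with thousands of object-frames. Validation
  therefore either pools independent acquisitions (unbiasedness against
  the empirical standard error) or samples one stationary frame from each
  of many acquisitions, where the binomial error model is exact.
* **Determinism.** Every stochastic stage (filament field, trajectories,
  rendering) derives its own seed from `config$seed`; a fixed seed gives
  bit-identical ground truth and movies. Ties in the assignment problem are
  resolved by sorting detections by (frame, x, y) before linking.
* **Degenerate inputs.** A frame with non-positive mean cannot be
  normalized and raises an error naming the frame; an empty image yields an
  empty detection set (not an error); a track with no motile steps reports
  missing speed; dwell statistics refuse to summarize a table in which all
  events are censored.

## Parameter defaults at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `pixel_size_nm` | 143 | camera calibration |
| `frame_interval_ms` | 154 (475 in presets) | acquisition interval |
| `n_frames` | 600 | series length |
| `motile_speed_um_s` | 1.0 | directed excursion speed |
| `bound_dwell_s` | 60 (control) / 25 (depleted) | mean bound sojourn |
| `free_dwell_s` | 5 (control) / 8 (depleted) | mean excursion time |
| `gate_radius_px` | 5 | linking gate (≈715 nm, above the 3 px criterion so motile steps stay linkable) |
| `min_frames` | 6 | track filter, strict "more than 5 frames" |
| `threshold_px` | 3.0 | immobile/motile displacement criterion |
| `radius_px` | 3 | association/colocalization radius |
| `max_gap_frames` | 0 | association runs are strictly consecutive |

The linking weights (`w_dist = 1`, `w_int = 0.5`, intensity differences
scaled by the median detection intensity) are declared defaults, not values
recovered from the original software, and are exposed for adjustment. The
same holds for the "more than 5 frames" reading: the filter keeps tracks of
at least 6 detections, and the threshold is an argument, not a constant.

## Known limitations

* Object-based association cannot distinguish recruitment onto a
  compartment from fusion with it; both appear as one run.
* The 3 px criterion interacts with the frame interval: slower acquisitions
  make slow transport visible as motile steps, faster ones hide it. Speeds
  recovered from different intervals are not directly comparable.
* Dwell means on series shorter than ~10 mean dwells are biased low by
  truncation even with censoring handled correctly; report the series
  length with any dwell estimate.
* The LAP solver is exact but O(n³) per frame pair; fields with hundreds of
  simultaneous detections will be slow in pure R.
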