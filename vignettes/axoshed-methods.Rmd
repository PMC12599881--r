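---
title: "Models and methods behind axoshed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axoshed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

axoshed quantifies organelle transport and transcellular shedding in
live-imaged optic nerves. This vignette documents the models each stage
assumes, the tunable parameters and their defaults, the numerical choices,
and what the synthetic validation does and does not establish about real
data.

## The transport model and the 0.1 µm/s rule

A trace's velocity is its **net displacement over the observed span**,
`v = (s_last − s_first)/(t_last − t_first)`, not the mean of instantaneous
segment speeds. Net velocity is robust to frame-to-frame jitter and matches
how speed over a fixed imaging period is reported in this literature.
Objects are classified *moving* when |v| ≥ 0.1 µm/s — the boundary counts as
moving — anterograde when v > 0 (the `+s` axis is the eye→brain direction,
supplied by the path orientation), retrograde when v < 0. Direction-changing
objects are classified by the same net velocity; no reversal segmentation is
attempted.

Per-trace observations shorter than 5 frames are excluded from percentages
(`min_trace_len`); with 60 frames at 1 Hz this removes detections too brief
to classify against a 0.1 µm/s boundary.

## The synthetic scene generator

`scene_config()` fixes the study conditions; the defaults are the baseline
the pipeline is validated under:

| parameter | default | unit | rationale |
|---|---|---|---|
| `nerve_diameter_um` | 30 | µm | nerve calibre at the imaged location |
| `n_frames`, `frame_interval_s` | 60, 1 | — | 1 min at 1 Hz single-plane series |
| `z_step_um` | 1 | µm | z-scan step |
| `state_fractions` | (0.50, 0.25, 0.25) | — | about half of axonal mitochondria stationary, balanced anterograde/retrograde |
| `speed_mean_antero_um_s`, `speed_mean_retro_um_s` | 0.63, 0.78 | µm/s | mean moving speeds used as generative settings |
| `speed_sd_um_s` | 0.15 | µm/s | realistic spread; draws truncated at 0.15 µm/s so truth classes stay unambiguous |
| `stationary_net_sd_um_s` | 0.02 (truncated at ±0.05) | µm/s | docked organelles drift slowly; Brownian-bridge jitter (SD 0.05 µm) is added around the drift so the *net* velocity is exactly the drawn value |
| `coloc_coupling` | (0.6, 0.2, 0.2) | — | stationary-enriched channel-B carriage |
| `extra_axonal_fraction` | 0.15 | — | mid-range of the 3–36% spanned by the reported conditions |
| `surface_share_of_outside` | 0.239 | — | surface share of extra-axonal signal |
| `protrusion_density_per_100um`, `protrusion_mito_prob` | 0.47, 0.603 | — | protrusion frequency and mitochondria content |
| `psf_sigma_um` | 0.25 | µm | diffraction-scale Gaussian PSF |
| `spot_amplitude`, `noise_model` | 30, Poisson + Gaussian(SD 2) | a.u. | spot-peak SNR ≈ 5 |

Particles are rendered as isotropic Gaussian spots; real mitochondria are
elongated, so a capsule (spherocylinder) renderer
(`render_capsule_volume()`) is provided for the shape-contrast tests.
Axons are straight, slightly jittered parallel lanes — real axons are not a
regular lattice, and perfectly regular lanes would also make registration
ambiguous. Noise is scaled-Poisson shot noise plus additive Gaussian read
noise. No photobleaching, myelin structure or non-axonal autofluorescence is
modelled; spot amplitudes and SNR are free parameters because imaging SNR is
not a quantity the analysis pins down.

Scale of the validation experiments: the headline transport-recovery run
uses 4000 particles as 20 fields of view of 200 particles (40 axons ×
100 µm each, ≈5 objects per 100 µm of axon). This density is deliberately
below densely labelled tissue so that a fully automatic tracer remains
fair: the semi-automatic workflow the analysis mirrors allowed manual
curation of ambiguous objects, which a test harness cannot reproduce.

## Registration

Per-frame rigid translation is estimated by phase correlation against the
first frame: mean subtraction and a Hann window suppress non-circular edge
artifacts, the whitened cross-power spectrum is regularized at 1% of its
peak modulus, and the integer peak is refined by locally upsampled
cross-correlation (zoomed DFT, 10×). Because a fixed window biases large
shifts toward zero, estimates above 2 px are iterated on the residual. The
shift series is then smoothed with a running median (width 7): stage drift
is smooth in time, so high-frequency excursions are estimation noise.
Finally a second pass re-estimates residuals against the temporal mean of
the registered registration channel — a sharp static anchor in which moving
objects have washed out — and the stack is interpolated once with the
combined shifts.

Registration uses the particle channel itself (default: first traced
channel): with about half the objects stationary, the correlation peak is
dominated by the static constellation. The structural membrane channel is
deliberately not used — a nerve-parallel band constrains only the transverse
axis. A known limitation: the stationary pool itself drifts slowly
(sub-boundary net velocities), so the "static" anchor disperses over a
minute and a slowly growing longitudinal registration error remains at the
end of a 60-frame series; the test suite verifies it stays below the scale
that affects net-velocity classification (per-class velocities from
drift-free and drift-injected-then-registered stacks agree within
0.05 µm/s).

## Swaths, kymographs and one-object-one-trace

The nerve contour is the boundary of the largest Otsu-threshold component of
a temporal mean projection; its principal axis and perpendicular diameter
come from a PCA of the component pixels. The interior is tiled with
abutting, non-overlapping parallel bands (default width 1.5 µm, the
mid-range of the 0.9–1.8 µm working range; whether bands should abut or
overlap is not externally specified, and abutting was chosen). Kymographs
sample intensity along each band at pixel steps, reducing across the width
with `max` by default (preserves punctate ridges; `mean` available).

A PSF-blurred object near a band edge also leaves a ghost ridge in the
neighbouring band, which would multiply-count objects. Three mechanisms
address this:

* **Subpixel transverse localization.** The two width-samples bracketing the
  cross-width maximum locate the spot centre by the Gaussian log-intensity
  ratio, even when the centre lies outside the band. Detections whose centre
  falls outside their own band are discarded (*band ownership*).
* **Transverse-aware linking.** Links are refused beyond 0.8 µm of
  transverse motion, traces are split at sustained transverse jumps
  (chimera change-points), and identity swaps at ridge crossings are
  repaired by testing whether exchanging post-crossing segments lowers the
  summed linear-fit residuals.
* **Cross-swath deduplication and gap closing.** Traces that overlap in
  time, agree in position (≤0.6 µm), velocity (≤0.15 µm/s) and transverse
  position (≤0.35 µm) are one object; the copy sampled nearer its own band
  centre is kept. Temporally disjoint fragments are joined when one trace's
  velocity extrapolation predicts the other's start. Raw and deduplicated
  stationary counts are both reported, since large immotile objects are the
  ones liable to multiple counting.

## Co-localization

A channel-A trace is co-localized when some channel-B trace lies within
`max_dist_um` (default 0.5 µm — about two pixels; no published numeric
criterion exists for the visual matching this mirrors, so the value is
exposed and sensitivity-tested) for at least `min_overlap_frac` (default
0.5) of A's observed frames, with one-to-one greedy assignment by mean
distance, ties broken toward longer overlap.

## Volumetry

The axon mask is the Otsu threshold of the axon-filling (cytoplasmic LC3b)
channel, cleaned of components under 27 voxels, optionally closed with an
exact Euclidean closing (separable distance transform). For *signal*
channels the default threshold is **background-referenced** — mean + 5 SD of
the voxels below the 99th percentile — rather than Otsu: punctate signal
occupies well under a percent of the voxels, and histogram-splitting
methods then split the background distribution instead and count noise as
signal, inflating the outside fraction (background is mostly extra-axonal by
volume). Supra-threshold components under 8 voxels
are discarded as noise. Fractions are computed on voxel volumes, not object
counts; an object-wise variant assigns whole components by their centroid.
The surface shell is the set of voxels within `d_um` (default 3 µm, an
astrocyte-soma-scale depth; "on the surface" has no published numeric
definition) of the nerve boundary on either side, built from the distance
transform.

Z-stacks emulate frame-averaged acquisitions, so only stationary deposits
are rendered — moving objects blur out of such scans and are
under-represented in them by construction.

## Dystrophies and events

Surface area for sphericity is estimated by the **co-area formula**: the
summed gradient magnitude of a Gaussian-smoothed indicator (σ = 1.5 voxels,
isotropic in physical units) times the voxel volume. Voxel-face counting
overestimates curved surfaces by ~50% and cannot give meaningful Wadell
sphericity (Ψ = π^⅓(6V)^⅔/A, the definition adopted because no formula is
stated alongside the original sphericity measurements); the co-area estimate
converges as voxels shrink — the test suite asserts that a rendered unit
sphere's |Ψ − 1| shrinks between 0.2 and 0.1 µm voxels and is below 0.05 at
the finer resolution.

A protrusion is an **asymmetric** radial excursion: one side of the
centerline exceeds the tube radius by ≥0.5 µm over a run ≥0.6 µm wide *and*
by at least twice the contralateral excursion (default k = 2; symmetric
swellings fail this test). Density is `100 × count / axon length`.

Event tracking takes a repetitive z-scan series (30-s intervals for 5 min or
2-min intervals for 10 min) with an axon mask per timepoint. The protrusion
is the supra-threshold component outside the axon mask nearest its previous
position; the minimum 3D Euclidean boundary distance (0 while touching;
distances are 3D, not per-slice) defines `pinch_time` as the first separated
timepoint. Intensities are measured in the protrusion and in the axon
"directly beneath" it (axon voxels within the protrusion's along-axon
footprint ±1 µm), each normalized so a same-axon away-region (≥5 µm from the
event, matched length) has mean 1. Kinds: *detached* (never touching),
*pinching-off* (touching then separated), *loading* (attached, protrusion
intensity rising while the beneath-intensity falls), otherwise *swelling*.
The persistence bound is `n_surviving × span / n_tracked`: survivors
persisted at least the whole span and non-survivors at least zero.

## Statistics

The aggregation order is fixed: object → animal → group. Every measure is
first averaged per animal, and N is the number of animals, never the number
of objects. Comparisons are unpaired two-tailed Welch t-tests for two
groups, or one-/two-way ANOVA followed by Tukey's HSD; for movement-class
panels all class × group contrasts enter the adjustment but only the
stationary between-group contrasts are flagged for display, matching the
convention of showing only the stationary comparisons. Stars: \*p<0.05,
\*\*p<0.01, \*\*\*p<0.001.

## What the synthetic validation shows — and what it does not

Passing recovery tests establishes that the *algorithms* are unbiased under
the generator's assumptions: Gaussian spots on straight jittered lanes,
Poisson-Gaussian noise, rigid translation drift, stationary objects that
are genuinely docked. Real nerves add curved axons, heterogeneous spot
shapes and intensities, photobleaching, non-rigid tissue motion and
sub-resolution axon packing; none of these are modelled, and the recovery
tolerances (±3 percentage points on fractions, ±5% on speeds, ±4 points on
volumetric fractions, ±5 points on coupling) should be read as lower bounds
on the error to expect in tissue. Two deliberate generator simplifications
matter for interpretation: moving objects never reverse, so net-velocity
classification is exact on truth; and z-stacks contain only stationary
deposits, so volumetric recovery does not test motion blur.

## Reproducibility

All randomness flows from explicit seeds (`scene_config(seed = )`, stage
seeds derived from the pipeline's master seed); identical configuration and
seed give byte-identical summary JSON. The acceptance script
(`scripts/acceptance.R`) recomputes the package's worked-example quantities
from scratch at run time.
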