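# axoshed

Quantitative live-imaging analysis of axonal organelle transport and
transcellular shedding in the optic nerve.

## The problem

Retinal ganglion cell (RGC) axons running through the optic nerve carry
mitochondria and mitophagy machinery (the receptor OPTN, the autophagosome
protein LC3b) in three populations — stationary, anterograde and retrograde —
and shed some of their stationary cargo into the surrounding tissue through
membranous protrusions ("exophers"/evulsions) that are then degraded by
astrocytes. Quantifying this biology from live microscopy requires four
linked measurements:

1. **Transport classification.** A 1-min, 1-Hz single-plane time series is
   rigidly registered, the nerve contour traced, the interior divided into
   0.9–1.8 µm parallel swaths, and a kymograph extracted per swath. Objects
   are detected and linked into traces; a trace's net velocity
   `v = (s_last − s_first)/(t_last − t_first)` classifies it as *moving*
   when |v| ≥ 0.1 µm/s (boundary inclusive; anterograde when v > 0,
   eye→brain) and *stationary* otherwise.
2. **Trace co-localization.** Traces from two channels (e.g. mitochondria
   and OPTN) are matched one-to-one when they stay within 0.5 µm for at
   least half of their observed frames, and the co-localized fraction is
   reported per movement class.
3. **Extra-axonal volumetry.** In z-stacks (1 µm steps), the cytoplasmic
   LC3b signal builds the axon mask; for each signal channel,
   `pct_outside = 100 × (supra-threshold voxels outside the mask) / (all
   supra-threshold voxels)`, and the extra-axonal signal is split between a
   surface shell of the nerve and the parenchyma.
4. **Protrusion morphodynamics.** Asymmetric axolemmal protrusions are
   detected along sparse axons (linear density per 100 µm, fraction
   containing mitochondria, Wadell sphericity Ψ = π^⅓(6V)^⅔/A of their
   cargo), and repetitive z-scan series of single events are tracked:
   minimum bud–axon boundary distance, baseline-normalized loading curves,
   pinch-off calling and survival-based persistence bounds.

Every stage is validated against a synthetic optic-nerve scene generator
with exhaustive ground truth, so the whole pipeline can be checked by
parameter recovery: simulate with known state fractions, speeds, coupling
and extra-axonal fractions, run the full analysis, and compare.

## Worked example

```r
library(axoshed)

cfg <- scene_config(n_particles = 200, seed = 1003,
                    drift_per_frame_px = c(0.1, 0.1))
truth <- simulate_trajectories(cfg)
stack <- render_timelapse(truth, cfg, seed = 2003)
stack <- inject_drift(stack, cfg$drift_per_frame_px)$stack

res <- analyze_transport(stack)          # register -> contour -> swaths ->
                                         # kymographs -> traces
mt <- res$channels$mito$traces
mt$animal_id <- 1
summarize_movement(mt)$group
```

```
  movement_class n_animals mean_pct sem_pct mean_speed_um_s
1 anterograde            1     23.7      NA           0.604
2 retrograde             1     24.2      NA           0.745
3 stationary             1     52.2      NA              NA
```

The generator drew this scene's particles 53.0% stationary, 22.5%
anterograde and 24.5% retrograde, with mean speeds 0.63 (anterograde) and
0.78 µm/s (retrograde); the recovered percentages and speeds agree with the
realized truth within the pipeline's validated aggregate tolerances (±3
percentage points on fractions, ±5% on speeds over a 4000-particle
experiment; a single 200-particle field carries a few points of sampling
and tracking noise). Co-localization and
volumetry follow the same pattern:

```r
cs <- match_traces(res$channels$mito$traces, res$channels$mito$long,
                   res$channels$optn$traces, res$channels$optn$long)
cs$by_class                     # co-localized fraction per movement class

vz   <- render_zstack(scene_config(extra_axonal_fraction = 0.15, seed = 42))
mask <- build_axon_mask(vz)     # from the LC3b (axon-fill) channel
pct_outside(vz, "mito", mask)$pct_outside
#> [1] 17.8   # true voxel fraction for this seed: 15.0; tolerance +/- 4 points
```

A persistence bound from tracked protrusion counts (13 of 18 still present
after 8 min):

```r
persistence_bound(n_tracked = 18, n_surviving = 13, span_min = 8)
#> [1] 5.777778   # mean persistence of at least ~5.8 min
```

`run_pipeline(default_pipeline_config())` chains every stage
(simulate → register → kymograph → transport → co-localization → volumetry →
event tracking → per-animal statistics) and writes CSV/JSON reports; a thin
command-line front end lives in `inst/cli/axoshed.R`.

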