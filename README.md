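# colonysim

Agent-based simulation of bacterial microcolonies growing in monolayers,
with synthetic phase-contrast / fluorescence microscopy rendering and
pixel-accurate ground truth.

Deep-learning segmentation and tracking of microbes in microfluidic
live-cell imaging is bottlenecked by training data: pixel-perfect instance
masks are laborious to annotate. `colonysim` generates that data
synthetically. It grows virtual 2D colonies — polygonal cell agents that
elongate exponentially ($dL/dt = kL$) and divide under phenomenological
size-homeostasis rules ("timer": divide at age $\tau$; "sizer": divide at
length $L_{div}$), packed into a feasible monolayer by a rigid-body contact
solver — and renders them through a configurable degradation stack (ideal
raster → difference-of-Gaussians phase-contrast halo → uneven illumination →
additive/multiplicative pixel noise → quantization). Because the scene is
simulated, every annotation is exact by construction:

* YOLO detection boxes (normalized `0 cx cy w h` text lines),
* COCO instance-segmentation JSON (polygon segmentations),
* 16-bit instance label masks (TIFF),
* TrackMate-style lineage XML (spots + mother→daughter edges),
* watertight STL meshes of single cells for CFD,
* a batch dataset generator with a reproducibility manifest.

Intended users: bioimage-analysis groups training detectors/segmenters on
microbial phase-contrast data, and anyone needing parametrizable colonies
with known lineage ground truth.

## Worked example

Grow one founder cell for six hours under the default sizer model
(width 0.9 µm, division length 3.6 µm, 1 h mean doubling time, 10%
cell-to-cell variability), then render and annotate the final frame:

```r
library(colonysim)

model <- homeostasis_model("sizer", trigger_mean = 3.6, trigger_cv = 0.1,
                           rate_mean = log(2), rate_cv = 0.1)
cfg <- simulation_config(seed = 7, dt = 1/60, duration = 6, model = model)
trajectory <- run_simulation(cfg)
final <- trajectory[[length(trajectory)]]

cat("frames:", length(trajectory), "\n")
cat("final time (h):", final$time, "\n")
cat("final cell count:", nrow(final$agents), "\n")
cat("mean cell length (um):", round(mean(final$agents$length), 2), "\n")

rc <- render_config()           # 512 x 512 px, 0.09 um/pixel
frame <- render_phase_contrast(final, rc, seed = 7)
ann   <- annotate(final, rc)
cat("rendered depth:", attr(frame, "depth"), "bits; intensity range:",
    range(frame), "\n")
cat("annotated cells in frame:", length(ann$cells), "\n")
```

prints

```
frames: 13
final time (h): 6
final cell count: 45
mean cell length (um): 2.5
rendered depth: 16 bits; intensity range: 19062 57198
annotated cells in frame: 45
```

Six hours is about six doubling times, so one founder grows to ~45 cells
(heterogeneity desynchronizes the divisions, so the count is not exactly
64). Cells appear dark (minimum intensity ≈ 19k of 65535) on a bright
background (≈ 0.7 × 65535 ≈ 46k, pushed higher by the halo rim), and every
one of the 45 cells receives a clipped pixel polygon and a tight box.
`write_frame(frame, "frame.tif")`, `write_yolo(ann, "frame.txt")`,
`write_masks(ann, "mask.tif")` etc. persist the outputs.

A full training dataset — independent colonies snapshotted at densities
spanning a range, here the published 128-image configuration — is one call:

```r
spec <- dataset_spec(n_images = 128, image_size = 512, calibration = 0.09,
                     cell_count_range = c(0, 512), seed = 1)
generate_ground_truth_dataset(spec, dir = "dataset")
```

or from a shell:

```sh
Rscript inst/cli/colonysim dataset --seed 1 --output-dir dataset
Rscript inst/cli/colonysim simulate --config my_run.yml render.calibration=0.09
```

## Layout

* `R/geometry.R` — polygonal shape catalogue, exact areas, polygon clipping
* `R/agents.R` — cell state, growth, timer/sizer division, heterogeneity
* `R/placement.R`, `src/placement.cpp` — rigid-body overlap resolution
* `R/engine.R` — the simulation loop and RNG management
* `R/render.R` — phase-contrast / fluorescence image stack
* `R/outputs.R`, `R/mesh.R` — ground-truth emitters and mesh export
* `R/config.R`, `inst/cli/colonysim` — YAML configuration and CLI
* `vignettes/colonysim-methods.Rmd` — model assumptions, parameters, design
  decisions and limitations
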