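---
title: "Simulating bacterial microcolonies and their synthetic micrographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bacterial microcolonies and their synthetic micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Deep-learning segmentation of microbes in microfluidic live-cell imaging
needs large amounts of pixel-accurate ground truth, which is laborious to
annotate by hand. `colonysim` sidesteps the annotation bottleneck by growing
*virtual* monolayer microcolonies with an agent-based model and rendering
them as realistic phase-contrast (and fluorescence) frames — so every mask,
box and lineage link is known exactly, by construction.

This vignette describes the model, the degradation stack, the numerical
choices, and what the synthetic data does and does not capture.

## The agent-based colony model

Each cell is an independent agent with an id, a lineage link to its mother,
a pose (centroid position in µm, orientation in radians) and a shape from a
small catalogue — straight rod (spherocylinder), bent rod, coccoid and
ellipsoid — all represented as closed polygonal chains (32 vertices by
default). Cell *length* is always tip-to-tip, the way lengths are read off
micrographs. In R, the population is a data frame with one row per agent;
the per-step operations are vectorized over it.

### Growth

Single cells elongate exponentially, $dL/dt = kL$, the standard law for
bacterial single-cell growth; width stays constant through the cell cycle.
Exponential elongation gives closed forms for every test: after a step $dt$,
$L' = L e^{k\,dt}$ exactly.

### Division: timer and sizer homeostasis

Two phenomenological size-homeostasis rules are implemented:

* **timer** — divide when the cell's age reaches a threshold $\tau$ (hours);
* **sizer** — divide when its length reaches a threshold $L_{div}$ (µm).

Comparisons are inclusive (`>=`), so a cell exactly at its trigger divides;
with the strict inequality a cv = 0 population would never divide at a
commensurate step size. Eligibility is evaluated at the end-of-step clock
$t + dt$ and daughters are stamped with that birth time, which makes the
synchronous closed forms exact: one founder with a cv = 0 timer reaches
$2^n$ cells after $n$ trigger periods.

Division is symmetric fission: daughters of length $L/2$ are placed
end-to-end at $\pm L/4$ along the mother's axis, inheriting width, bend and
(up to a small Gaussian perturbation, default $\sigma = 0.05$ rad) the
mother's orientation. The angle perturbation produces the fan-out seen in
real monolayer colonies while keeping conservation testable at $\sigma = 0$:
total cell length is conserved exactly at each division, even when the
optional split-fraction noise redistributes length between the daughters.
Fluorescence is inherited per unit length, so total emission is conserved
across divisions; this is one documented, configurable choice among several
defensible ones.

Cell-to-cell heterogeneity comes from per-daughter draws of the elongation
rate and division trigger from lognormal distributions parametrized by an
arithmetic mean and coefficient of variation (positive support, standard
choice). The defaults emulate a *Corynebacterium*-like monolayer culture:
width 0.9 µm, sizer trigger 3.6 µm (birth length 1.8 µm), rate mean
$\ln 2\ \mathrm{h^{-1}}$ (1 h doubling time), cv 0.1 for both. An "adder"
rule is deliberately not implemented.

### Simulation loop and reproducibility

Per fixed time step (default 1 min): grow all agents, divide the eligible
ones, then restore a feasible packing. Snapshots go to output emitters every
`emit_every` steps. All randomness derives from one integer seed: founder
initialization and each daughter's parameter draw use a seed derived from
(seed, agent id), so results are independent of the order in which mothers
are processed and a run is bit-reproducible from its configuration. The
founder placement (uniform in a disc of five mean cell lengths) is a
declared choice.

## Overlap resolution

Growth and division make neighbours overlap; a physical colony cannot. The
placement module restores a feasible monolayer (strictly 2D — crowded cells
never escape out of plane) by rigid translations and small rotations only;
shape parameters are never touched. Letting cells rotate during resolution
produces the nematic alignment characteristic of rod-shaped colonies.

Since no 2D rigid-body engine is available as an R package, the solver is a
bespoke position-based scheme written in C++ (via Rcpp):

* every cell is bounded by the **capsule hull** of a short centerline
  polyline (a point for coccoids, the axis segment for rods and ellipsoids,
  a 9-point arc for bent rods, with the radius inflated by the sampling
  sagitta so the hull always contains the polygon outline);
* contacts are detected by segment–segment distances and resolved by damped
  Gauss–Seidel sweeps in a fixed pair order (deterministic);
* a sweep that would increase the summed penetration depth is retried at
  half step from the previous state, so the logged convergence series is
  monotone non-increasing by construction.

The solver stops when every pair's capsule penetration is below a per-pair
allowance $\delta_{ij} = \text{tol} \cdot \min(A_i, A_j) / \min(L_i, L_j)$.
Because the overlap region lies inside both cells, its extent is at most
$\min(L_i, L_j)$ and its thickness at most the capsule penetration, so this
allowance guarantees a polygon overlap area of at most `tol` times the
smaller cell's area — the default `tol = 0.01` is sub-pixel at 0.09
µm/pixel. The guarantee is verified in the tests with an exact, independent
polygon-intersection oracle (ear-clipping triangulation plus
Sutherland–Hodgman clipping, itself cross-checked against Monte-Carlo
point-in-polygon sampling). The per-iteration log records total capsule
penetration depth, a cheap strictly-correlated proxy for total overlap
area; computing exact polygon intersections each sweep would be
prohibitively slow at colony scale.

Degenerate contacts (coincident closest points) fall back to a
deterministic direction derived from the first cell's orientation. An
optional rectangular arena confines the colony; by default the plane is
unbounded.

## The image generation stack

Rendering maps the world (µm) onto a raster with origin at the top left;
pixel $(r, c)$ covers $[(c-1)s, cs) \times [(r-1)s, rs)$ µm with $s$ the
calibration (0.09 µm/pixel by default), camera centered on the colony
centroid. Annotations use the same convention, so masks and boxes are
pixel-consistent with the frames.

The stages, applied in fixed order:

1. **Ideal image** — background intensity 0.7, cell interior 0.25 (dark
   cells on a bright field; declared defaults). Boundary pixels are
   anti-aliased by 4×4 subpixel sampling, which keeps the rasterized
   intensity deficit equal to the cell area to within 2%.
2. **Phase-contrast halo** — two Gaussian blurs of the deviation from
   background combined into a difference-of-Gaussians,
   $out = bg + w_i G_{\sigma_i}\!*d - w_o G_{\sigma_o}\!*d$. Defaults
   $\sigma_i = 1$, $\sigma_o = 6$ px, $w_i = 1$, $w_o = 0.4$ were tuned so a
   line profile through a cell shows the characteristic bright rim outside a
   dark interior; the mechanism (combined blurs) is the physical caricature,
   the constants are configurable. Blurs use `EBImage::gblur`, which
   conserves flux for interior content.
3. **Uneven illumination** — multiplication by $1 + a f(x,y)$ with $f$ a
   unit-amplitude, approximately zero-mean smooth random surface. The
   default field is a random 2nd-order polynomial (typical flat-field
   error, cheap); a blurred-white-noise field with a configurable
   correlation length is the alternative, for which `illumination_scale`
   is meaningful.
4. **Pixel noise** — $out = \mathrm{clip}(img(1+\varepsilon_m) +
   \varepsilon_a)$ with independent Gaussian draws per pixel. Raising the
   additive sigma is the supported way to emulate deteriorated image
   quality; the histogram correlation between clean and degraded frames
   decreases monotonically with it.
5. **Quantization** to 8 or 16 bits (16-bit TIFF by default).

Fluorescence frames rasterize each cell's total emission uniformly over its
area, convolve with a Gaussian point spread function and add a constant
background; flux is conserved within 2% away from the borders. Optional
Poisson shot noise uses a configurable photon scale. Phase-contrast and
fluorescence channels draw independent noise.

What the renderer deliberately does **not** model: physical phase-contrast
optics (Zernike ring, wave propagation), camera fixed-pattern noise, focus
drift, debris, chamber walls and cell lysis. Networks trained on these
frames therefore see idealized colonies with realistic first-order
statistics (intensity histograms, halo profiles, density), not every real-
world artifact — passing the package's tests demonstrates internal
consistency of the generator, not equivalence to any particular microscope.

## Ground-truth emitters

All emitters run off a per-frame annotation (pixel polygons clipped to the
image, tight boxes, lineage links):

* **YOLO**: one `0 cx cy w h` line per cell, normalized to [0, 1].
* **COCO**: polygon segmentations, `[x, y, w, h]` boxes, shoelace areas,
  one category `"cell"`; round-trips losslessly through `read_coco()`.
* **Label masks**: 16-bit TIFF, background 0, per-frame labels 1..n; the
  rare residual-overlap pixel goes to the smaller cell id (deterministic).
* **TrackMate-style XML**: one spot per cell per frame, edges along each
  cell's frames and from a mother's last spot to each daughter's first; a
  minimal Model/AllSpots/AllTracks skeleton sufficient for import, since no
  particular schema version is targeted. Lineage edges are restricted to
  emitted frames: if both a mother and her daughter never appear in any
  emitted frame, the connecting edge cannot be represented.
* **STL meshes** for CFD: watertight surfaces of revolution (capsule,
  sphere, revolved ellipse; bent rods bend the straight capsule mesh about
  its neutral axis, which preserves volume), written as binary STL. Volumes
  agree with closed forms to < 1% at the default resolution and converge as
  resolution grows.

## The batch dataset generator

`generate_ground_truth_dataset()` reproduces the published use-case
configuration: 128 images of 512 × 512 px at 0.09 µm/pixel with 0–512 cells
per frame. Each image is an **independent colony** (stated in the
manifest), seeded `seed + image_index`; per-image target counts are drawn
log-uniformly over the count range — a density spread that benefits
detector training — with a small share (about 3%) of empty frames when the
range starts at 0. A colony is simulated until its population first reaches
its target and snapshotted; if the dividing step overshoots past the range
maximum, the last in-range state is used, so manifest counts always lie in
the configured range. The manifest records per-image seed, target and
achieved count, making the whole dataset bit-reproducible.

At the default study conditions the full 128-image dataset takes a few
minutes on one CPU core; the deeper acceptance checks in
`tests/testthat/test-acceptance.R` use the full configuration, while unit
tests run smaller colonies (tens of cells) and frames (128–256 px) chosen
to exercise the same code paths at a fraction of the cost.

## Configuration and command line

A single YAML document configures everything; unknown keys are rejected by
name and all validation failures are reported together. Missing sections
fall back to the documented defaults (an empty file is a valid, fully
default configuration — this also means the `dataset` section is always
present after loading). `inst/cli/colonysim` exposes `simulate` and
`dataset` subcommands with `--config`, `--seed`, `--output-dir`,
`--duration`, `--dt` and dotted-key overrides such as
`render.calibration=0.09`. Every run writes a manifest embedding the fully
resolved configuration, from which the run can be reproduced bit-exactly.

## Known limitations

* The sizer cv = 0 closed form (all birth lengths exactly $L_{div}/2$)
  holds when the founder starts at $L_{div}/2$ and the doubling time is an
  integer number of steps; otherwise discrete-time overshoot shifts birth
  lengths by up to a factor $e^{k\,dt}$. `init_world()` defaults the sizer
  founder length to `trigger_mean / 2` accordingly.
* The placement solver guarantees the overlap tolerance only on
  convergence; extremely crowded synchronous division bursts can exhaust
  `max_iterations` (default 1000), which is reported via the `converged`
  attribute and the run log.
* Monolayer only: no out-of-plane escape, no nutrient or signalling
  coupling, no motility, no cell death.
* The bent-rod mesh bend transform preserves watertightness and volume but
  is not an exact offset surface of the 2D outline's 3D sweep at high
  curvature.
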