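---
title: "Automated RBC tracking and cell-free layer measurement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated RBC tracking and cell-free layer measurement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheotrack)
```

## The measurement problem

In vitro blood flow experiments image suspensions of red blood cells (RBCs)
flowing through microchannels — a ~100 µm glass capillary under a confocal
fluorescence system (labeled cells appear bright), or a
bifurcation/confluence polymer channel under brightfield (cells appear dark,
and a bright cell-depleted plasma margin, the cell-free layer or CFL, hugs
the walls). Two quantities are extracted from such sequences: individual
cell trajectories (from which velocity profiles, mean squared displacement
and lateral dispersion follow) and the CFL thickness along the walls. Both
are classically measured by hand in ImageJ — clicking each cell centroid
frame by frame, or projecting the stack and tracing the layer with the wand
tool. `rheotrack` automates both measurements and keeps the manual-era
baselines (Z-projections, ROI tonality profiles, wand selection) available
so the two routes can be compared on equal footing.

## Tracking pipeline

The chain is: optional ROI crop → polarity normalization (cells bright) →
median denoising → automatic global threshold → binarization → connected
components with properties → area filter → frame-to-frame linking → short
track elimination.

**Intensity model and threshold.** The working assumption is a bimodal
intensity histogram: many background pixels and a smaller bright object
population. The automatic level is the intermeans (Ridler–Calvard) fixed
point: starting from the global mean, the level moves to the midpoint of
the two class means until stationary,
$t_{k+1} = \tfrac12\left(\overline{I_{\le t_k}} + \overline{I_{> t_k}}\right)$.
The midpoint-of-class-means criterion is only meaningful as an iteration —
a single evaluation depends on an arbitrary initial split — so the
iterated form is the default, with `max_iter = 1` available for the
single-pass variant. Numerical choices: convergence tolerance `tol = 0.5`
intensity levels (half a quantization step of 8-bit data, so iteration
stops as soon as the level stops moving on the intensity grid),
`max_iter = 100`, pixels exactly at the level belong to the background
class (objects are *strictly* brighter), and a constant image raises an
error rather than inventing a split. The result depends only on the
histogram, never on pixel layout.

**Denoising.** A square median filter (default 5×5 for tracking, 3×3 for
the CFL chain) removes shot noise while preserving edges. Borders are
padded by edge replication by default: zero padding darkens frame borders,
which on fluorescence data creates a phantom bright-to-dark edge and on
brightfield data a phantom core. A `pad = "zero"` switch preserves
bit-compatibility with implementations that pad with zeros. Even kernel
sizes are rejected rather than silently offset, keeping the operator
symmetric.

**Components and properties.** Blobs are connected components of the
binary image; area is the pixel count and the centroid is the unweighted
mean of member pixel coordinates. Coordinates follow the image convention
throughout: 0-based, x = column increasing rightward, y = row increasing
downward, so the centroid of the single pixel (row r, col c) is (c, r).
Default connectivity is 8 — diagonal touches merge, which biases toward
fewer, larger components, the right behavior for compact cell images.
The Sobel gradient magnitude (3×3 kernels, edge-replicated borders) is
computed for edge display; object extraction operates on the filled
binarized components because filled-component centroids are better defined
than edge rings. The area filter is inclusive at both bounds; its purpose
is physical (platelets are smaller and white blood cells larger than
RBCs), and intensity-based filtering is deliberately not used.

**Linking.** The per-frame detections are joined into trajectories by
greedy globally-nearest-pair assignment: among all (active track, new blob)
pairs within the displacement gate, repeatedly commit the closest pair.
Ties in distance break by lower track id, then lower blob label, which
makes the output invariant to per-frame detection order. Unmatched blobs
start new tracks; unmatched tracks terminate — there is no gap closing, so
a cell lost for one frame starts a new fragment. This matches the
downstream policy of *eliminating* short fragments rather than repairing
them, and at the low cell densities these experiments are run at
(hematocrit kept near 12% precisely to make tracking reliable) greedy
nearest-pair is equivalent to optimal assignment in practice. The default
`min_track_length = 10` (inclusive) encodes that a trajectory of about ten
positions is the lower limit worth analyzing; the exact cutoff is
configurable.

**Trajectory statistics.** No standard fixes the exact estimator, so the
package adopts the field's usual conventions and documents them: the
time-averaged MSD over frame lags,
$\mathrm{MSD}(\tau) = \langle |\mathbf r(t+\tau) - \mathbf r(t)|^2 \rangle_t$
(µm² after calibration), and the lateral dispersion coefficient
$D_{yy}(t) = \langle (y(t) - y(0))^2 \rangle_{\text{tracks}} / (2t)$
(µm²/s), with t counted from each track's start. Both are checked against
closed forms (ballistic MSD = (vτ)²; constant-y tracks give zero Dyy) and
a brute-force double-loop oracle in the tests.

## CFL pipeline

The chain is: per-frame 3×3 median → temporal extreme-intensity image →
binarization into the cell-core mask → wall-referenced per-column
thickness → region summaries.

**Extreme-intensity image.** The sequence is collapsed into one image that
records, per pixel, the strongest cell signal ever seen there. For
fluorescence (cells bright) that is the pixel-wise maximum; for brightfield
(cells dark) it is the pixel-wise minimum of the raw frames — identically
the maximum after intensity inversion, presented on the native scale. The
design point is deliberate: a literal maximum of a brightfield sequence
would mark a pixel as "core" only if a cell covered it in *every* frame,
whereas the cell-signal extreme marks it as soon as a cell covered it
*once*. Only the latter yields the expected appearance — a dark traversed
core with the cell-free margin keeping the highest intensity (white) near
the walls — and is robust at moderate cell densities. Monotonicity (adding
a frame never decreases any pixel) holds in the cell-signal polarity and
is tested there.

**Core mask and thickness.** The projection is binarized at the intermeans
level (or a manual override — image quality and threshold level are the
two dominant sensitivities of this measurement, so the override mirrors
the judgment a user would apply). The wall is supplied as a piecewise
linear polyline of (x, y) vertices, mirroring the manual step of selecting
the channel wall; automatic wall detection is deliberately out of scope.
Thickness at column x is the scan distance from the wall row to the first
core pixel, downward for an upper wall, upward for a lower wall. Columns
whose scan path contains no core pixel are reported as missing (`NA`),
never clamped to zero — silent zeros would bias region means downward.
Scanning is always along image columns, a perpendicular-to-flow
approximation valid for horizontally oriented channels; near a bifurcation
apex the true wall normal rotates away from the column direction and the
column scan overestimates the local thickness. This is a documented
limitation, and region windows are best placed away from the apex.

**Regions and comparison.** Measurement regions (the A–F windows along a
bifurcation/confluence) carry no standard numeric definition; they are
user-supplied, non-overlapping column windows. Summaries use the sample
(n−1) standard deviation, like the projection `std` (matching the ImageJ
convention; a population switch exists). `compare_cfl_methods()` reports
per-region mean differences and a Spearman rank correlation of per-column
thickness over the shared measured columns — rank correlation because the
interesting question across methods is whether the spatial *behavior*
agrees, not the absolute offset.

## Synthetic scenes and what they do (not) show

Both generators produce seed-reproducible stacks with exact ground truth,
so every pipeline stage is testable without external recordings.

**Capillary scenes** (`simulate_capillary()`) default to the fluorescence
working conditions: 640×480 px at 100 frames/s, a 100 µm channel, 20 cells
in view, 8-bit. The pixel scale defaults to 0.45 µm/px, placing the
channel across ~222 rows and an 8 µm cell at ~18 px diameter — consistent
with a 40× objective on that sensor. Cells are rendered as anisotropic
Gaussian spots (σ = cell_radius/2 = 4.5 px), not hard disks: soft edges
exercise the threshold and produce realistic sub-pixel centroids.
Velocities follow plug or Poiseuille advection,
$v(y) = v_{max}\,(1 - (2(y-y_c)/w)^2)$ with v_max = 4 px/frame by default;
background 20, peak cell amplitude 150, optional Gaussian noise, quantized
and clipped to the integer intensity grid. Cells are laid out in
constant-y lanes whose spacing exceeds the thresholded blob footprint and
whose spawn window keeps every cell in frame for the whole sequence: blobs
never merge and ground truth covers every frame. This emulates the
deliberate low-hematocrit experimental choice; it also means the generator
does *not* exercise occlusion, cell overlap, defocus, photobleaching or
illumination drift — a perfect score here shows the chain is correct under
its stated assumptions, not that it would survive dense suspensions
(splitting touching cells is explicitly out of scope).

**CFL scenes** (`simulate_cfl_channel()`) default to the brightfield
working conditions: 800×600 px at 200 frames/s, walls at rows 150/449
(300 px channel), background 220 / cell level 40, true CFL 15 px, 8-bit.
Dark Gaussian cells ride x-periodic lanes (4 px lane spacing, 24 px
in-lane spacing, random per-lane phases, recycled across the image edge)
under plug advection — the core of a concentrated suspension moves with a
blunted, plug-like profile — so that over the sequence every core pixel is
traversed and the extreme projection fills the core. Rendering is clipped
to the occupancy band `[wall + cfl(x), opposite wall − cfl(x)]`: the band
edge *is* the ground-truth CFL boundary, because the plasma layer is by
definition strictly cell-free. Walls and the true CFL may vary per column
(diverging/converging walls approximate a bifurcation geometry as straight
segments). The dense, streaky core is a realism compromise: it emulates
the high local hematocrit of a real core, not individually resolvable
cells.

## Verification scales

The test suite checks every operator against an independent brute-force
oracle (explicit sorts, convolutions, BFS flood fills, double loops,
per-pixel reductions) on randomized small frames, and both pipelines
against ground truth at the working scales: tracking on 20 cells × 50
frames at 640×480 (noise-free: 100% recall required, one track per cell,
centroid error ≤ 0.5 px; at 5% dynamic-range noise: ≥ 95% identity-correct
recovery), and CFL on 200-frame 800×600 scenes (constant 15 px truth
within 1 px; sinusoidal truth 10 + 5 sin(2πx/200) px with per-column RMSE
≤ 1.5 px). These sizes keep the default suite near one minute on a single
CPU while exercising the full working resolution. `scripts/acceptance.R`
reruns exactly these recoveries from scratch and emits the numbers as
JSON.

## Known limitations

- Touching or overlapping cells are not split; the tracker assumes the
  segmentation yields one component per cell.
- No gap closing: occlusion or a missed detection fragments a trajectory.
- Brightness/shading correction is limited to polarity inversion;
  flat-field correction of illumination drift is out of scope, and the
  synthetic scenes are generated without drift accordingly.
- CFL scan direction is fixed to image columns (see above).
- BMP input is not supported (TIFF and PNG are); video containers and
  proprietary camera formats are out of scope.
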