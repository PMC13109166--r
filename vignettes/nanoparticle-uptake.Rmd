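---
title: "Quantifying label-free nanoparticle uptake from 3D confocal stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying label-free nanoparticle uptake from 3D confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npuptake)
```

## The measurement problem

Metal nanoparticles of 80–150 nm scatter visible light strongly, so a
confocal microscope can localize them label-free by collecting back-scattered
excitation light in reflection mode, while fluorescence channels image the
cell body (e.g. cytosolic GFP) and the plasma membrane. From one multichannel
3D stack we want three things:

1. **counts** — how many particles are in the field of view, and how many of
   them are *inside* a cell;
2. **concentrations** — particles per unit cell volume (µm⁻³) or membrane
   surface (µm⁻²), averaged over replicate images and binned to nominal
   incubation times;
3. **aggregation state** — whether a detected spot is one particle or an
   unresolvable clump of k particles.

All three rest on the same segmentation core, so the package is organized
around it.

## Segmentation model

Each channel is low-pass filtered with a separable 3D Gaussian (default
σ = 1 voxel on every axis, reflecting the common object-counting protocol of
applying one width in all three directions even though voxels are
anisotropic; a `sigma_um` option gives a physically isotropic blur instead).
The filtered volume is thresholded globally — either at a user-supplied
cutoff, mirroring the manual threshold choice of an interactive workflow, or
automatically by Otsu's criterion on a 256-bin histogram of the full volume,
which is the reproducible default. Voxels at or above the cutoff are
foreground; connected components under 26-connectivity (the common default
of 3D object counters; 6 and 18 are available) become objects.

Per object we measure the voxel count, physical volume
(count × dz·dy·dx), the unweighted centroid of member voxel centers,
integrated density (sum of intensities over member voxels, measured on the
filtered channel by default because that is the image the counting ran on;
`measure_on_raw` switches to the raw channel), surface area, and whether the
object touches the stack boundary. Surface area is estimated by
exposed-face counting: each member-voxel face adjacent to background or to
the volume edge contributes its physical face area. This estimator is exact
with respect to its own definition — which makes it testable against a
brute-force oracle — but systematically overestimates the area of a smooth
surface (by a factor approaching 1.5 for a sphere); we accept that bias in
exchange for exactness, and document it rather than hide it behind an
untestable smoothing scheme.

Coordinates are 0-based voxel indices ordered (z, y, x); physical positions
are voxel-center positions, `(index + 0.5) × spacing`. Thresholding uses
`>=` so that the mask includes voxels exactly at the cutoff; the size filter
is applied before edge exclusion. These conventions are arbitrary but fixed,
because every downstream count depends on them.

## In/out assignment

A particle is assigned to the cell whose segmented volume contains its
centroid, treated as a dimensionless point: the physical centroid is floored
to a voxel index and looked up in the cell label volume. Particles whose
centroid falls on background — including particles sitting *on* a cell
surface — count as outside. We deliberately model no membrane-shell
compartment: the lipid bilayer (~4 nm) is far thinner than any particle
here, so a micrometre-thick "membrane region" would be an arbitrary
construct, and a binary in/out split is the cleanest defensible convention.
Cells touching the image boundary are retained with their truncated in-FOV
volumes (adherent cells essentially always touch the frame); this biases
concentration denominators slightly low for cropped cells and is documented
rather than corrected.

Cell segmentation defaults to the whole-cell (`cellbody`) channel with a
minimum object size of 1000 voxels to reject debris; the membrane channel
can be selected instead via configuration. Particle segmentation uses
minimum size 0 and an unbounded maximum so that aggregates are never
discarded.

## Time profiles

Because one stack takes ~20 min to acquire, replicates of a nominal
incubation time are acquired in a window around it (images started at 40,
60 and 80 min all represent the 1 h point). `bin_time_points()` assigns each
image to the nearest bin center within a halfwidth (defaults: centers 1–8 h,
halfwidth 0.5 h) and reports the mean and the *population* standard
deviation (divisor n) of the pooled concentration per bin — the population
convention matches the error bars this kind of study reports. Images falling
outside every bin are returned unbinned rather than silently dropped.

## Aggregate discrimination

Scattered intensity grows linearly with scatterer volume for particles in
this size range (shape effects neglected in first approximation), so a
k-particle aggregate — unresolvable at ~250 nm lateral resolution — appears
as a single spot carrying k-fold the integrated intensity of a primary
particle. The distribution of per-object integrated densities is therefore
modeled as a Gaussian mixture whose class means are **constrained** to
k·μ₁, k = 1..K, with μ₁, the per-class spreads and the mixing weights free.
The hard constraint is what makes a 4%-abundance class identifiable with
only ~500 objects; free per-class σ’s are used because no variance model is
imposed by the physics (counting noise, partial-volume effects and CV of the
particle size all contribute).

Fitting is by EM. The M-step update for μ₁ is a precision-weighted
regression of intensities on multiplicities,

μ₁ ← Σᵢₖ rᵢₖ k xᵢ/σₖ² ⁄ Σᵢₖ rᵢₖ k²/σₖ².

μ₁ is initialized at the histogram mode; five seeded restarts jitter it by
±20% and the best likelihood is kept; convergence is a relative
log-likelihood change below 1e-8 or 500 iterations; spreads are floored at
10⁻³ of the data scale so a near-empty class cannot collapse onto a single
point. K is selected from 1..K_max (default 4 — beyond four-fold intensity
the counts are typically too sparse to support more peaks) by minimal BIC
with 2K free parameters (μ₁, K spreads, K−1 weights). Class fractions are
reported from the mixture weights; an area-ratio mode (`area_fractions()`)
is provided for workflows that report peak-area proportions — for
well-separated peaks the two coincide, since each class density integrates
to its weight.

`fit_intensity_volume()` checks the linearity premise by ordinary least
squares of integrated density against apparent volume. One caveat worth
stating precisely: for diffraction-limited Gaussian spots the *apparent*
(thresholded) volume grows like `(ln(peak/threshold))^(3/2)` while
integrated density grows like k, so even a noiseless rendered scene gives a
mildly convex relation with r² around 0.95–0.98, not 1.0. A strong positive
slope with r² in that range is the expected signature of the linear
intensity–volume physics under thresholded detection, not evidence against
it.

## The synthetic generator

Real stacks from this kind of experiment are not publicly deposited, so the
package ships a generator that emulates the acquisition instead, and every
pipeline claim is validated against its ground-truth manifests.

* **Geometry** — default 25 layers of 512×512 px at (0.3, 0.06, 0.06) µm,
  i.e. a quarter-size frame of the typical 1024² acquisition at the same
  sampling, 16-bit scale. Full-frame scenes are available through the spec;
  the quarter frame keeps a full validation suite in minutes.
* **Cells** — non-overlapping ellipsoids (random semi-axes in configurable
  ranges, optionally randomly oriented), filled uniformly in the cellbody
  channel; the membrane channel is the one-voxel inner boundary shell. Cell
  placement samples all cell bounding boxes jointly and restarts the whole
  configuration on a clash, since greedy placement deadlocks when cells are
  large relative to the FOV.
* **Particles** — sub-resolution point scatterers rendered as 3D Gaussian
  PSF spots (default FWHM 0.25 µm lateral, 0.75 µm axial) whose *integrated*
  intensity is drawn per particle from Normal(k·μ₁, (cv·k·μ₁)²), with
  μ₁ = 43 000 a.u. and cv = 0.10 by default and multiplicities from
  (0.88, 0.08, 0.03, 0.01). Aggregates are single spots with k-fold
  intensity — they are below the resolution limit by construction. Inside
  particles are planted ≥ 1 µm from the (discrete) cell boundary; outside
  particles sit at the lowest z-layer, where non-internalized particles
  settle on the coverslip.
* **Noise** — constant background (100 a.u.), optional Poisson noise on the
  expected counts, Gaussian read noise (sd 15 a.u.), clipping and 16-bit
  quantization. With the default spot peak of ≈ 820 a.u. above background,
  the peak SNR is ≈ 55. No instrument noise statistics were available to
  calibrate against; these defaults are chosen to be comfortably detectable
  while leaving the algorithmic behavior, not the noise, as the object
  under test, and oracle tests switch noise off entirely.
* **Determinism** — a single seed in the scene spec drives every draw;
  identical specs give bitwise identical stacks and manifests.

What the generator does *not* emulate: optical crosstalk between channels,
depth-dependent PSF aberrations, fluorophore photophysics, non-ellipsoidal
cell shapes, cell motion, and spatially structured background. Passing the
validation suite therefore demonstrates that the *analysis* is correct under
the stated imaging model; it does not certify performance on any particular
instrument's noise floor.

## Validation conditions and known limitations

The built-in validation plants the study's printed values: a 522-object
field for detection; the (88, 8, 3, 1)% aggregate composition at
μ₁ = 43 000 a.u. (secondary peak 2μ₁ ≈ 8.6×10⁴ a.u.) for the mixture; and
pooled concentrations of 0.1 µm⁻³ (the 150 nm-sphere maximum) and 0.01 µm⁻³
(urchin level) for the end-to-end pipeline, using two flat ~950 µm³ cells.
Problem sizes: detection and concentration scenes run at 25×512×512 voxels;
mixture experiments use 20 replicates of 522 intensities.

Two quantitative caveats, both consequences of diffraction rather than
implementation choices:

* **Axial merging.** With an axial PSF σ of ~0.32 µm plus the σ = 1 voxel
  analysis blur, two spots separated by 1–1.4 µm *along z* merge into one
  object above the Otsu cutoff. At a planted density of 0.1 µm⁻³ with a 1 µm
  minimum separation this loses ~5 % of objects (and the recovered
  concentration sits correspondingly low, well inside a ±10 % band). Exact
  count recovery needs separations of ~2 µm, which the exactness tests use.
* **Convex intensity–volume relation.** As described above, r² of the
  intensity–volume regression saturates near 0.95–0.98 on noiseless scenes.

Other limitations: no watershed splitting of touching cells (two adherent
cells segmented as one object pool their volumes); no deconvolution or
local thresholding; manual per-image thresholds from interactive protocols
cannot be reproduced when they were never recorded — the Otsu default exists
precisely to remove that irreproducibility.
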