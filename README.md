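# npuptake

Label-free quantification of nanoparticle uptake by cells from multichannel
3D confocal stacks.

Gold (and other metal) nanoparticles scatter visible light strongly enough
to be imaged without any label: a confocal microscope collects the
back-scattered excitation in reflection mode, while fluorescence channels
image the whole cell body (e.g. cytosolic GFP) and the plasma membrane.
`npuptake` turns such stacks into uptake statistics for researchers studying
nanoparticle–cell interactions (drug delivery, photothermal therapy,
nanotoxicology):

- **3D segmentation core** — separable Gaussian blur, global thresholding
  (Otsu's criterion on a 256-bin histogram, or a fixed cutoff), 3D
  connected-component labeling (6/18/26-connectivity, compiled), and
  per-object measurement: centroid, voxel count, physical volume, surface
  area (exposed-face counting), integrated density.
- **In/out assignment** — a particle belongs to the cell whose segmented
  volume contains its centroid (the point `(index + 0.5)·spacing`); a
  centroid on background, including particles sitting *on* a cell, counts
  as outside. No membrane-shell compartment is modeled.
- **Uptake statistics** — per-cell counts and concentrations (µm⁻³ and
  µm⁻²), field-of-view summaries (inside fraction, pooled concentration
  `n_inside / Σ cell volume`), and replicate binning into nominal
  incubation time points with population-SD error bars.
- **Aggregate discrimination** — the distribution of per-object integrated
  densities is decomposed by an EM-fitted Gaussian mixture whose class
  means are *constrained* to integer multiples k·μ₁ of the primary-particle
  intensity (scattering scales with scatterer volume, so a k-particle
  clump carries k-fold intensity), with model order chosen by BIC:

  p(x) = Σₖ₌₁ᴷ πₖ · N(x; k·μ₁, σₖ²)

- **Synthetic scene generator** — ellipsoidal cells, PSF-shaped
  sub-resolution scatterers with k-fold aggregate intensities, Poisson/read
  noise, 16-bit quantization, and a ground-truth manifest, so the whole
  pipeline is testable without microscope data.

## Worked example

Simulate a default scene (two cells, 50 particles planted inside, 30 on the
coverslip outside) and run the analysis chain:

```r
library(npuptake)

spec <- scene_spec(n_particles_inside = 50, n_particles_outside = 30, seed = 1)
sc   <- simulate_scene(spec)
sp   <- sc$stack$spacing

particles <- segment_objects(get_channel(sc$stack, "reflection"),
                             filter_params(1), segmentation_params(), sp)
cells     <- segment_objects(get_channel(sc$stack, "cellbody"),
                             filter_params(1),
                             segmentation_params(min_voxels = 1000), sp)
labs <- attr(cells, "labels")
labs[!array(labs %in% cells$object_id, dim(labs))] <- 0L

assignment <- assign_particles(particles, labs, sp)
records    <- summarize_cells(assignment, cells)
summarize_fov(assignment, records)
#>   n_particles_total n_inside_total inside_fraction total_cell_volume_um3
#> 1                77             47       0.6103896              812.7205
#>   pooled_conc_per_um3
#> 1          0.05783046
```

77 of the 80 planted spots are detected (three pairs closer than ~1.4 µm
along z merge — a diffraction effect, not a bug), 47 of the 50 inside
particles are recovered inside, and the pooled concentration is the inside
count divided by the summed segmented cell volume. The aggregate analysis
runs on the detected objects' integrated densities:

```r
fit_multiplicity_mixture(particles$integrated_density, K_max = 4, seed = 1)
#> integer-multiple Gaussian mixture: K = 2 classes over 77 objects
#>   primary intensity mu1 = 3.146e+04 a.u. (BIC 1643.6)
#>   k=1: mean 3.146e+04, sigma 5.61e+03, fraction 87.2%
#>   k=2: mean 6.293e+04, sigma 4.02e+04, fraction 12.8%
```

The mixture finds the primary population and a two-fold-intensity minority —
the planted composition was 88% singles. (Image-measured integrated density
sits below the planted total spot intensity because only above-threshold
voxels are summed; the *ratios* between classes, which carry the aggregation
information, are preserved.)

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/npuptake.R simulate --spec scene.yaml --seed 7 --out s1.tif
Rscript inst/scripts/npuptake.R run --config cfg.yaml
Rscript inst/scripts/npuptake.R aggregate --objects out/s1/particles.csv --kmax 4 --seed 7 --out agg
```

See `vignettes/nanoparticle-uptake.Rmd` for the model, parameter and
design-choice documentation.

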