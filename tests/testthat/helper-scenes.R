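# Shared scene builders for the tests. Sizes are kept small so individual
# tests run in seconds; acceptance-scale scenes live in test-acceptance.R.

# a compact single-cell scene with a handful of primary particles; the cell
# is a flat adherent-style ellipsoid large enough to host ~10 particles at
# 2 um pairwise separation and 1 um from its boundary
small_scene_spec <- function(seed = 42, n_in = 5, n_out = 5,
                             min_sep = 2, noise = 15, ...) {
  scene_spec(dims = c(15, 288, 288), n_cells = 1,
             cell_semi_axes_um = list(z = c(1.8, 2.0), y = c(6.5, 7.0),
                                      x = c(6.5, 7.0)),
             random_orientation = FALSE,
             n_particles_inside = n_in, n_particles_outside = n_out,
             multiplicity_probs = c(1, 0, 0, 0),
             min_separation_um = min_sep, read_noise_sd = noise,
             seed = seed, ...)
}

# a no-cell field of well-separated spots (detection-only scenes)
spot_field_spec <- function(n, seed, dims = c(15, 192, 192), min_sep = 2,
                            multiplicity_probs = c(1, 0, 0, 0), ...) {
  scene_spec(dims = dims, n_cells = 0, n_particles_inside = 0,
             n_particles_outside = n,
             multiplicity_probs = multiplicity_probs,
             min_separation_um = min_sep, seed = seed, ...)
}

# two flat axis-aligned cells filling most of the field; particles planted
# inside at a target number concentration (per um^3 of true mask volume)
concentration_scene <- function(target_conc, seed,
                                dims = c(25, 512, 512)) {
  spec <- scene_spec(
    dims = dims, n_cells = 2,
    cell_semi_axes_um = list(z = c(2.8, 3.0), y = c(6.2, 6.8),
                             x = c(11.5, 12.3)),
    random_orientation = FALSE, n_particles_inside = 0,
    n_particles_outside = 30, multiplicity_probs = c(1, 0, 0, 0),
    seed = seed)
  withr::with_seed(seed, {
    cells <- generate_cells(spec)
    true_volume <- sum(cells$cells$volume_um3)
    spec$n_particles_inside <- as.integer(round(target_conc * true_volume))
    particles <- place_particles(spec, cells$labels)
    rendered <- render_stack(spec, cells, particles)
    list(stack = rendered$stack, truth = rendered$truth,
         true_volume = true_volume,
         planted_conc = spec$n_particles_inside / true_volume)
  })
}

# the default analysis chain: segment both channels, assign, summarize
analyze_stack <- function(stack, cell_min_voxels = 1000) {
  sp <- stack$spacing
  particles <- segment_objects(get_channel(stack, "reflection"),
                               filter_params(1), segmentation_params(), sp)
  cells <- segment_objects(get_channel(stack, "cellbody"), filter_params(1),
                           segmentation_params(min_voxels = cell_min_voxels),
                           sp)
  labs <- attr(cells, "labels")
  keep <- array(labs %in% cells$object_id, dim(labs))
  labs[!keep] <- 0L
  assignment <- assign_particles(particles, labs, sp)
  records <- summarize_cells(assignment, cells)
  list(particles = particles, cells = cells, labels = labs,
       assignment = assignment, records = records,
       fov = summarize_fov(assignment, records))
}

# intensity draws at the aggregation study composition
draw_intensities <- function(n, seed, probs = c(0.88, 0.08, 0.03, 0.01),
                             mu1 = 43000, cv = 0.10) {
  withr::with_seed(seed, {
    k <- sample.int(length(probs), n, replace = TRUE, prob = probs)
    list(k = k, x = rnorm(n, k * mu1, cv * k * mu1))
  })
}
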