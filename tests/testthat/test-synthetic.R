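test_that("scene spec validates its physical invariants", {
  expect_error(scene_spec(multiplicity_probs = c(0.5, 0.4)), "sum to 1")
  expect_error(scene_spec(psf_fwhm_um = c(0.2, 0.25, 0.25)),
               "axial")
  expect_error(scene_spec(min_separation_um = -1), ">= 0")
  expect_error(scene_spec(mu1_intensity = 0), "mu1_intensity")
})

test_that("cell generation: empty scene, analytic volume, disjoint masks", {
  none <- generate_cells(scene_spec(n_cells = 0, dims = c(5, 32, 32)),
                         seed = 1)
  expect_true(all(none$labels == 0L))
  expect_equal(nrow(none$cells), 0)

  # voxelized ellipsoid volume approaches (4/3) pi a b c
  spec <- scene_spec(dims = c(40, 256, 256),
                     spacing = voxel_spacing(0.3, 0.1, 0.1), n_cells = 1,
                     cell_semi_axes_um = list(z = c(5, 5), y = c(10, 10),
                                              x = c(10, 10)),
                     random_orientation = FALSE)
  g <- generate_cells(spec, seed = 2)
  expect_equal(g$cells$volume_um3, 4 / 3 * pi * 5 * 10 * 10,
               tolerance = 0.02)

  # two requested cells produce strictly disjoint labels
  two <- generate_cells(scene_spec(
    dims = c(20, 256, 256), n_cells = 2,
    cell_semi_axes_um = list(z = c(1.5, 2), y = c(2, 3), x = c(2, 3))),
    seed = 3)
  expect_equal(sort(unique(as.integer(two$labels))), c(0L, 1L, 2L))
  expect_equal(nrow(two$cells), 2)
  # membrane shell is inside the mask and thin
  expect_true(all(two$labels[two$membrane] > 0))
  expect_lt(sum(two$membrane), sum(two$labels > 0))
})

test_that("particle placement respects counts, separations and truth flags", {
  spec <- small_scene_spec(seed = 4, n_in = 10, n_out = 10, min_sep = 1)
  cells <- generate_cells(spec, seed = 4)
  p <- place_particles(spec, cells$labels, seed = 4)
  expect_equal(sum(p$inside), 10)
  expect_equal(sum(!p$inside), 10)
  # outside particles sit at the coverslip (lowest z layer)
  expect_true(all(p$z_um[!p$inside] < spec$spacing[["dz"]]))
  # inside flags consistent with the mask
  d <- dim(cells$labels)
  for (i in which(p$inside)) {
    v <- floor(c(p$z_um[i] / 0.3, p$y_um[i] / 0.06, p$x_um[i] / 0.06))
    expect_gt(cells$labels[v[1] + 1, v[2] + 1, v[3] + 1], 0)
  }
  # pairwise separation, exhaustively
  pos <- as.matrix(p[, c("z_um", "y_um", "x_um")])
  dm <- as.matrix(dist(pos))
  expect_gte(min(dm[upper.tri(dm)]), spec$min_separation_um)
})

test_that("multiplicity draws follow the stated distribution", {
  probs <- c(0.88, 0.08, 0.03, 0.01)
  spec <- spot_field_spec(522, seed = 6, dims = c(15, 512, 512), min_sep = 1,
                          multiplicity_probs = probs)
  cells <- generate_cells(spec, seed = 6)
  p <- place_particles(spec, cells$labels, seed = 6)
  counts <- tabulate(p$k, 4)
  # each class count within its binomial 99% interval
  for (k in 1:4) {
    bounds <- qbinom(c(0.005, 0.995), 522, probs[k])
    expect_gte(counts[k], bounds[1])
    expect_lte(counts[k], bounds[2])
  }
})

test_that("rendered spots carry the specified integrated intensity", {
  base <- list(dims = c(25, 96, 96), n_cells = 0, n_particles_inside = 0,
               background_level = 0, read_noise_sd = 0)

  # empty scene renders an identically zero reflection channel
  empty <- do.call(scene_spec, c(base, list(n_particles_outside = 0,
                                            seed = 1)))
  sc0 <- simulate_scene(empty)
  expect_true(all(get_channel(sc0$stack, "reflection") == 0))

  # a single particle placed mid-volume: spot integral equals the drawn
  # intensity within PSF truncation (< 1%) and quantization
  spec <- do.call(scene_spec, c(base, list(n_particles_outside = 0,
                                           seed = 2)))
  cells <- list(labels = array(0L, c(25, 96, 96)),
                membrane = array(FALSE, c(25, 96, 96)),
                cells = data.frame())
  part <- data.frame(particle_id = 1L, z_um = 3.7, y_um = 2.9, x_um = 2.9,
                     k = 1L, inside = FALSE, cell_id = 0L)
  r <- render_stack(spec, cells, part, seed = 5)
  got <- sum(get_channel(r$stack, "reflection"))
  expect_equal(got, r$truth$particles$intensity_au, tolerance = 0.01)

  # k = 2 doubles the integral relative to k = 1 (no CV)
  spec0 <- do.call(scene_spec, c(base, list(n_particles_outside = 0,
                                            intensity_cv = 0, seed = 3)))
  p1 <- part; p2 <- transform(part, k = 2L)
  s1 <- render_stack(spec0, cells, p1, seed = 7)
  s2 <- render_stack(spec0, cells, p2, seed = 7)
  ratio <- sum(get_channel(s2$stack, "reflection")) /
    sum(get_channel(s1$stack, "reflection"))
  expect_equal(ratio, 2, tolerance = 0.005)

  # saturating parameters are reported, not clipped silently
  hot <- do.call(scene_spec, c(base, list(n_particles_outside = 0,
                                          mu1_intensity = 1e9,
                                          intensity_cv = 0, seed = 4)))
  expect_error(render_stack(hot, cells, part, seed = 8), "saturate")
})

test_that("apparent spot size reflects the PSF, not the particle", {
  # sub-resolution scatterers appear at the diffraction-limited size: the
  # rendered lateral FWHM matches the PSF FWHM within 10%
  spec <- scene_spec(dims = c(25, 96, 96), n_cells = 0,
                     n_particles_inside = 0, n_particles_outside = 0,
                     background_level = 0, read_noise_sd = 0,
                     intensity_cv = 0, seed = 1)
  cells <- list(labels = array(0L, c(25, 96, 96)),
                membrane = array(FALSE, c(25, 96, 96)),
                cells = data.frame())
  part <- data.frame(particle_id = 1L, z_um = 3.75, y_um = 2.88,
                     x_um = 2.88, k = 1L, inside = FALSE, cell_id = 0L)
  r <- render_stack(spec, cells, part, seed = 2)
  ch <- get_channel(r$stack, "reflection")
  zi <- which.max(apply(ch, 1, max))
  prof <- ch[zi, , which.max(apply(ch[zi, , ], 2, max))]
  half <- max(prof) / 2
  above <- which(prof >= half)
  fwhm_um <- (max(above) - min(above) + 1) * 0.06
  expect_equal(fwhm_um, 0.25, tolerance = 0.10)
})

test_that("identical spec and seed give bitwise identical scenes", {
  a <- simulate_scene(small_scene_spec(seed = 11))
  b <- simulate_scene(small_scene_spec(seed = 11))
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$particles, b$truth$particles)
  c <- simulate_scene(small_scene_spec(seed = 12))
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("full pipeline recovers planted populations on clean scenes", {
  # exact totals, in/out split and per-cell counts at 2 um separation
  for (seed in c(21, 22, 23)) {
    sc <- simulate_scene(small_scene_spec(seed = seed, n_in = 6, n_out = 6))
    res <- analyze_stack(sc$stack)
    expect_equal(res$fov$n_particles_total, 12)
    expect_equal(res$fov$n_inside_total, 6)
    truth_by_cell <- table(sc$truth$particles$cell_id[
      sc$truth$particles$inside])
    expect_equal(sum(res$records$n_particles_inside > 0),
                 length(truth_by_cell))
  }

  # at the 1 um study separation, dense fields can merge axially close
  # pairs; recovery stays above 95%
  sc <- simulate_scene(spot_field_spec(200, seed = 29,
                                       dims = c(25, 384, 384), min_sep = 1))
  objs <- segment_objects(get_channel(sc$stack, "reflection"),
                          filter_params(1), segmentation_params(),
                          sc$stack$spacing)
  expect_gte(nrow(objs) / 200, 0.95)
  expect_lte(nrow(objs), 200)
})
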