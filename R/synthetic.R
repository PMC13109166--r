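FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Specify a synthetic acquisition scene
#'
#' Describes a synthetic multichannel 3D stack emulating a label-free uptake
#' acquisition: ellipsoidal cells (whole-cell fill plus a one-voxel membrane
#' shell), sub-resolution point scatterers rendered as PSF-shaped spots whose
#' *integrated* intensity is k-fold the primary-particle intensity for
#' k-particle aggregates, optional Poisson and Gaussian read noise, and
#' 16-bit quantization. Defaults mirror a typical confocal geometry:
#' quarter-frame 512 x 512 pixels at 60 nm, 25 layers at 0.3 um, diffraction
#' limit ~0.25 um FWHM lateral and 0.75 um axial, 16-bit scale.
#'
#' @param dims stack extents `c(nz, ny, nx)` in voxels.
#' @param spacing a [voxel_spacing()].
#' @param n_cells number of cells to place (>= 0).
#' @param cell_semi_axes_um list with elements `z`, `y`, `x`, each a
#'   `c(min, max)` range in um from which ellipsoid semi-axes are drawn.
#' @param random_orientation rotate each ellipsoid by a uniform random 3D
#'   rotation.
#' @param n_particles_inside,n_particles_outside planted particle counts;
#'   outside particles sit at the lowest z-layer (the coverslip).
#' @param multiplicity_probs probabilities of multiplicity k = 1..4
#'   (must sum to 1).
#' @param mu1_intensity mean integrated intensity of a single particle (a.u.).
#' @param intensity_cv per-class coefficient of variation of the integrated
#'   intensity.
#' @param psf_fwhm_um PSF full width at half maximum, `c(z, y, x)` um; the
#'   axial width must be at least the lateral one.
#' @param background_level constant background added to every voxel (a.u.).
#' @param read_noise_sd Gaussian read noise standard deviation (a.u.); 0
#'   disables it.
#' @param photon_noise draw each voxel from a Poisson at its expected value.
#' @param min_separation_um minimum pairwise distance between particles.
#' @param inside_margin_um minimum distance of inside particles from the cell
#'   boundary (and of outside particles from any cell).
#' @param cell_fill_intensity,membrane_intensity fluorescence fill levels
#'   (a.u.) for the cellbody and membrane channels.
#' @param seed integer seed; all draws of a [simulate_scene()] run flow from
#'   it.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(dims = c(nz = 25, ny = 512, nx = 512),
                       spacing = voxel_spacing(0.3, 0.06, 0.06),
                       n_cells = 2,
                       cell_semi_axes_um = list(z = c(2.5, 3.2),
                                                y = c(4.5, 6.0),
                                                x = c(6.0, 7.5)),
                       random_orientation = TRUE,
                       n_particles_inside = 50,
                       n_particles_outside = 30,
                       multiplicity_probs = c(0.88, 0.08, 0.03, 0.01),
                       mu1_intensity = 43000,
                       intensity_cv = 0.10,
                       psf_fwhm_um = c(z = 0.75, y = 0.25, x = 0.25),
                       background_level = 100,
                       read_noise_sd = 15,
                       photon_noise = FALSE,
                       min_separation_um = 1,
                       inside_margin_um = 1,
                       cell_fill_intensity = 3000,
                       membrane_intensity = 3000,
                       seed = 1) {
  spacing <- as_voxel_spacing(spacing)
  dims <- as.integer(unlist(dims))
  if (length(dims) != 3 || any(dims < 1)) stop("dims must be 3 positive extents")
  # YAML 1.1 reads a bare `y:` mapping key as boolean TRUE; undo that so
  # scene files need not quote the axis name
  names(cell_semi_axes_um)[names(cell_semi_axes_um) == "TRUE"] <- "y"
  if (!all(c("z", "y", "x") %in% names(cell_semi_axes_um))) {
    stop("cell_semi_axes_um needs ranges for all of z, y, x")
  }
  cell_semi_axes_um <- lapply(cell_semi_axes_um[c("z", "y", "x")],
                              function(r) {
    r <- as.numeric(unlist(r))
    if (length(r) == 1) r <- c(r, r)
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] > r[2]) {
      stop("each semi-axis range must be a positive (min, max) pair in um")
    }
    r
  })
  p <- as.numeric(multiplicity_probs)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("multiplicity_probs must be non-negative and sum to 1")
  }
  fw <- as.numeric(psf_fwhm_um)
  if (length(fw) != 3 || any(fw <= 0)) stop("psf_fwhm_um must be 3 positive widths")
  if (fw[1] < max(fw[2:3])) stop("axial PSF width must be >= lateral width")
  if (min_separation_um < 0 || inside_margin_um < 0) {
    stop("separations must be >= 0")
  }
  if (mu1_intensity <= 0 || intensity_cv < 0) {
    stop("mu1_intensity must be > 0 and intensity_cv >= 0")
  }
  structure(list(
    dims = setNames(dims, c("nz", "ny", "nx")), spacing = spacing,
    n_cells = as.integer(n_cells), cell_semi_axes_um = cell_semi_axes_um,
    random_orientation = isTRUE(random_orientation),
    n_particles_inside = as.integer(n_particles_inside),
    n_particles_outside = as.integer(n_particles_outside),
    multiplicity_probs = p, mu1_intensity = mu1_intensity,
    intensity_cv = intensity_cv,
    psf_sigma_um = setNames(fw * FWHM_TO_SIGMA, c("z", "y", "x")),
    background_level = background_level, read_noise_sd = read_noise_sd,
    photon_noise = isTRUE(photon_noise),
    min_separation_um = min_separation_um,
    inside_margin_um = inside_margin_um,
    cell_fill_intensity = cell_fill_intensity,
    membrane_intensity = membrane_intensity,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

uniform_rotation <- function() {
  # QR of a Gaussian matrix with sign fix gives a Haar-uniform rotation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate non-overlapping ellipsoidal cell masks
#'
#' Places `spec$n_cells` solid ellipsoids (random semi-axes, optional random
#' orientation) in the field of view without overlap, labeled 1..n. The
#' membrane shell is the one-voxel-thick inner boundary of each mask (member
#' voxels with a 6-neighbor outside the mask), so the shell lies within the
#' cell.
#'
#' Draws from R's RNG; wrap in [withr::with_seed()] or pass `seed` for a
#' standalone deterministic call ([simulate_scene()] seeds the whole run
#' once).
#'
#' @param spec a [scene_spec()].
#' @param seed optional integer; when given the call is independently seeded.
#' @param max_tries placement retries per cell before giving up.
#' @return list with `labels` (integer 3D array), `membrane` (logical 3D
#'   array) and `cells` (data frame: `cell_id`, centers, semi-axes, voxel
#'   volume in um^3).
#' @export
generate_cells <- function(spec, seed = NULL, max_tries = 500) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            generate_cells(spec, NULL, max_tries)))
  }
  d <- unname(spec$dims)
  sp <- as.numeric(spec$spacing)
  L <- d * sp                     # physical extents (z, y, x) in um
  labels <- array(0L, dim = unname(d))
  meta <- list()

  if (spec$n_cells > 0) {
    # stage 1: sample all cell geometries jointly (cheap), restarting the
    # whole configuration on a clash — greedy one-at-a-time placement can
    # paint itself into a corner when cells are large relative to the FOV.
    # Disjoint bounding boxes guarantee disjoint masks.
    geom <- NULL
    for (try in seq_len(max_tries)) {
      cand <- vector("list", spec$n_cells)
      ok <- TRUE
      for (ci in seq_len(spec$n_cells)) {
        ax <- unname(vapply(c("z", "y", "x"), function(a) {
          r <- spec$cell_semi_axes_um[[a]]
          runif(1, r[1], r[2])
        }, numeric(1)))
        R <- if (spec$random_orientation) uniform_rotation() else diag(3)
        half_ext <- sqrt(rowSums((R %*% diag(ax))^2))  # bbox half-extent
        if (any(2 * half_ext > L)) { ok <- FALSE; break }
        center <- vapply(1:3, function(i) {
          runif(1, half_ext[i], L[i] - half_ext[i])
        }, numeric(1))
        clash <- ci > 1 && any(vapply(cand[seq_len(ci - 1)], function(b) {
          all(abs(center - b$center) < half_ext + b$half_ext)
        }, logical(1)))
        if (clash) { ok <- FALSE; break }
        cand[[ci]] <- list(ax = ax, R = R, center = center,
                           half_ext = half_ext)
      }
      if (ok) { geom <- cand; break }
    }
    if (is.null(geom)) {
      stop("could not place ", spec$n_cells, " non-overlapping cells in ",
           max_tries, " configuration attempts; shrink the cells or ",
           "enlarge the FOV")
    }
    # stage 2: voxelize the accepted configuration
    for (ci in seq_len(spec$n_cells)) {
      g <- geom[[ci]]
      vox <- ellipsoid_voxels(g$center, g$R, g$ax, d, sp)
      labels[vox] <- ci
      meta[[ci]] <- data.frame(
        cell_id = ci, center_z_um = g$center[1], center_y_um = g$center[2],
        center_x_um = g$center[3], semi_z_um = g$ax[1], semi_y_um = g$ax[2],
        semi_x_um = g$ax[3], voxel_count = length(vox),
        volume_um3 = length(vox) * prod(sp)
      )
    }
  }
  membrane <- inner_boundary(labels)
  cells <- if (length(meta) > 0) do.call(rbind, meta) else
    data.frame(cell_id = integer(0), center_z_um = numeric(0),
               center_y_um = numeric(0), center_x_um = numeric(0),
               semi_z_um = numeric(0), semi_y_um = numeric(0),
               semi_x_um = numeric(0), voxel_count = integer(0),
               volume_um3 = numeric(0))
  list(labels = labels, membrane = membrane, cells = cells)
}

# linear indices of voxels whose centers fall inside the rotated ellipsoid
ellipsoid_voxels <- function(center, R, semi_axes, dims, sp) {
  lo <- pmax(0L, as.integer(floor((center - sqrt(rowSums((R %*% diag(semi_axes))^2))) / sp - 0.5)))
  hi <- pmin(dims - 1L, as.integer(ceiling((center + sqrt(rowSums((R %*% diag(semi_axes))^2))) / sp - 0.5)))
  if (any(hi < lo)) return(integer(0))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  g <- expand.grid(z = zi, y = yi, x = xi, KEEP.OUT.ATTRS = FALSE)
  P <- cbind((g$z + 0.5) * sp[1] - center[1],
             (g$y + 0.5) * sp[2] - center[2],
             (g$x + 0.5) * sp[3] - center[3])
  U <- P %*% R                      # rotate into the ellipsoid frame
  inside <- rowSums(sweep(U, 2, semi_axes, `/`)^2) <= 1
  idx <- g[inside, , drop = FALSE]
  1L + idx$z + dims[1] * (idx$y + dims[2] * idx$x)
}

# member voxels with a 6-neighbor carrying a different label (or the volume
# boundary): the one-voxel-thick shell of each labeled object
inner_boundary <- function(labels) {
  boundary <- array(FALSE, dim(labels))
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- shift_labels(labels, axis, dir)
      boundary <- boundary | (labels > 0L & nb != labels)
    }
  }
  boundary
}

#' Plant particle positions with ground truth
#'
#' Samples exactly `n_particles_inside` continuous positions inside cell
#' masks at `inside_margin_um` or more from the (discrete) cell boundary,
#' and `n_particles_outside` positions in the background at the lowest
#' z-layer — the coverslip plane, where non-internalized particles settle —
#' at the same margin from any cell. All particles respect the pairwise
#' `min_separation_um`. Multiplicities are drawn from
#' `spec$multiplicity_probs`.
#'
#' @inheritParams generate_cells
#' @param cell_labels integer 3D label array from [generate_cells()].
#' @param max_tries rejection-sampling attempts per particle.
#' @return data frame with columns `particle_id`, `z_um`, `y_um`, `x_um`,
#'   `k` (multiplicity), `inside`, `cell_id` (0 when outside).
#' @export
place_particles <- function(spec, cell_labels, seed = NULL,
                            max_tries = 2000) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            place_particles(spec, cell_labels, NULL,
                                            max_tries)))
  }
  d <- unname(spec$dims)
  sp <- as.numeric(spec$spacing)
  boundary <- inner_boundary(cell_labels)
  bidx <- which(boundary)
  B <- vox_center_coords(bidx, d, sp)     # boundary voxel centers, um

  interior <- which(cell_labels > 0L)
  if (spec$n_particles_inside > 0 && length(interior) == 0) {
    stop("no cell interior available for inside particles")
  }
  floor_idx <- which(cell_labels[1, , , drop = FALSE] == 0L)  # z = 0 layer

  accepted <- matrix(numeric(0), ncol = 3)
  rows <- list()
  pid <- 0L

  sample_one <- function(inside) {
    for (try in seq_len(max_tries)) {
      if (inside) {
        v <- interior[sample.int(length(interior), 1)]
        i0 <- v - 1L
        zyx <- c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
        pos <- (zyx + runif(3)) * sp
        cell <- cell_labels[v]
      } else {
        v <- floor_idx[sample.int(length(floor_idx), 1)]
        i0 <- v - 1L                       # linear index within the z=0 slice
        zyx <- c(0, i0 %% d[2], i0 %/% d[2])
        pos <- (zyx + runif(3)) * sp
        # the continuous position must stay in a background voxel
        vox <- pmin(d - 1L, as.integer(floor(pos / sp)))
        if (cell_labels[1L + vox[1] + d[1] * (vox[2] + d[2] * vox[3])] != 0L) next
        cell <- 0L
      }
      if (nrow(B) > 0 && spec$inside_margin_um > 0) {
        dmin <- min(sqrt(colSums((t(B) - pos)^2)))
        if (dmin < spec$inside_margin_um) next
      }
      if (nrow(accepted) > 0) {
        dpar <- min(sqrt(colSums((t(accepted) - pos)^2)))
        if (dpar < spec$min_separation_um) next
      }
      return(list(pos = pos, cell = cell))
    }
    stop("particle placement infeasible after ", max_tries,
         " tries (",
         if (inside) "cell interiors too small" else "background too crowded",
         " for the requested counts and separations)")
  }

  n_total <- spec$n_particles_inside + spec$n_particles_outside
  ks <- if (n_total > 0) {
    sample.int(length(spec$multiplicity_probs), n_total, replace = TRUE,
               prob = spec$multiplicity_probs)
  } else integer(0)

  for (i in seq_len(spec$n_particles_inside)) {
    s <- sample_one(TRUE)
    pid <- pid + 1L
    accepted <- rbind(accepted, s$pos)
    rows[[pid]] <- data.frame(particle_id = pid, z_um = s$pos[1],
                              y_um = s$pos[2], x_um = s$pos[3],
                              k = ks[pid], inside = TRUE,
                              cell_id = as.integer(s$cell))
  }
  for (i in seq_len(spec$n_particles_outside)) {
    s <- sample_one(FALSE)
    pid <- pid + 1L
    accepted <- rbind(accepted, s$pos)
    rows[[pid]] <- data.frame(particle_id = pid, z_um = s$pos[1],
                              y_um = s$pos[2], x_um = s$pos[3],
                              k = ks[pid], inside = FALSE, cell_id = 0L)
  }
  if (pid == 0) {
    return(data.frame(particle_id = integer(0), z_um = numeric(0),
                      y_um = numeric(0), x_um = numeric(0), k = integer(0),
                      inside = logical(0), cell_id = integer(0)))
  }
  do.call(rbind, rows)
}

vox_center_coords <- function(lin_idx, dims, sp) {
  if (length(lin_idx) == 0) return(matrix(numeric(0), ncol = 3))
  i0 <- lin_idx - 1L
  cbind((i0 %% dims[1] + 0.5) * sp[1],
        ((i0 %/% dims[1]) %% dims[2] + 0.5) * sp[2],
        (i0 %/% (dims[1] * dims[2]) + 0.5) * sp[3])
}

#' Render a scene into a multichannel stack with ground truth
#'
#' Reflection channel: each particle contributes a 3D Gaussian PSF-shaped
#' spot whose integrated intensity is a per-particle draw from
#' `Normal(k * mu1, (cv * k * mu1)^2)` — aggregates are unresolvable
#' sub-resolution clumps carrying k-fold intensity. Cellbody channel: flat
#' fill of the cell masks; membrane channel: the one-voxel shell. The
#' constant background is added everywhere; optional Poisson noise is
#' applied to the expected counts, then Gaussian read noise; the result is
#' clipped to \[0, 65535\] and quantized to integers.
#'
#' @inheritParams generate_cells
#' @param cells result of [generate_cells()].
#' @param particles result of [place_particles()].
#' @param name stack identifier.
#' @param time_h optional nominal incubation time stored on the stack.
#' @return list with `stack` (a [multichannel_stack()], channels
#'   reflection/cellbody/membrane) and `truth` (a truth manifest: particle
#'   table with realized intensities, cell table, seed and spec echo).
#' @export
render_stack <- function(spec, cells, particles, seed = NULL,
                         name = "synthetic", time_h = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            render_stack(spec, cells, particles, NULL,
                                         name, time_h)))
  }
  d <- unname(spec$dims)
  sp <- as.numeric(spec$spacing)
  sig <- as.numeric(spec$psf_sigma_um)

  particles$intensity_au <- if (nrow(particles) > 0) {
    pmax(rnorm(nrow(particles), particles$k * spec$mu1_intensity,
               spec$intensity_cv * particles$k * spec$mu1_intensity),
         .Machine$double.eps)
  } else numeric(0)

  refl <- array(0, dim = unname(d))
  # per-axis peak density of the sampled PSF: used for the saturation check
  peak_gain <- prod(sp / (sqrt(2 * pi) * sig))
  max_expected <- if (nrow(particles) > 0) {
    max(particles$intensity_au) * peak_gain + spec$background_level
  } else spec$background_level
  if (max_expected > 65535) {
    stop("spot peaks would saturate the 16-bit range (expected peak ",
         round(max_expected), " a.u.); reduce mu1_intensity or widen the PSF")
  }

  for (i in seq_len(nrow(particles))) {
    pos <- c(particles$z_um[i], particles$y_um[i], particles$x_um[i])
    rng <- lapply(1:3, function(a) {
      lo <- max(0L, as.integer(floor((pos[a] - 4 * sig[a]) / sp[a])))
      hi <- min(d[a] - 1L, as.integer(ceiling((pos[a] + 4 * sig[a]) / sp[a])))
      lo:hi
    })
    gz <- sp[1] / (sqrt(2 * pi) * sig[1]) *
      exp(-0.5 * (((rng[[1]] + 0.5) * sp[1] - pos[1]) / sig[1])^2)
    gy <- sp[2] / (sqrt(2 * pi) * sig[2]) *
      exp(-0.5 * (((rng[[2]] + 0.5) * sp[2] - pos[2]) / sig[2])^2)
    gx <- sp[3] / (sqrt(2 * pi) * sig[3]) *
      exp(-0.5 * (((rng[[3]] + 0.5) * sp[3] - pos[3]) / sig[3])^2)
    spot <- particles$intensity_au[i] *
      outer(outer(gz, gy), gx)
    refl[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] <-
      refl[rng[[1]] + 1L, rng[[2]] + 1L, rng[[3]] + 1L] + spot
  }

  body <- spec$cell_fill_intensity * (cells$labels > 0L)
  memb <- spec$membrane_intensity * cells$membrane

  finish <- function(ch) {
    ch <- ch + spec$background_level
    if (spec$photon_noise) {
      ch <- array(rpois(length(ch), pmax(ch, 0)), dim(ch))
    }
    if (spec$read_noise_sd > 0) {
      ch <- ch + rnorm(length(ch), 0, spec$read_noise_sd)
    }
    round(pmin(65535, pmax(0, ch)))
  }
  refl <- finish(refl)
  body <- finish(body)
  memb <- finish(memb)

  data <- array(0, dim = c(3, unname(d)))
  data[1, , , ] <- refl
  data[2, , , ] <- body
  data[3, , , ] <- memb
  stack <- multichannel_stack(
    data, spec$spacing, c(reflection = 1, cellbody = 2, membrane = 3),
    name = name, time_h = time_h
  )
  truth <- list(
    particles = particles,
    cells = cells$cells,
    seed = spec$seed,
    spec = spec[c("dims", "n_cells", "n_particles_inside",
                  "n_particles_outside", "multiplicity_probs",
                  "mu1_intensity", "intensity_cv", "background_level",
                  "read_noise_sd", "photon_noise", "min_separation_um",
                  "inside_margin_um")]
  )
  list(stack = stack, truth = truth)
}

#' Simulate a complete scene
#'
#' Seeds the RNG once from `spec$seed` and runs [generate_cells()],
#' [place_particles()] and [render_stack()] in sequence; identical specs
#' give bitwise identical stacks and manifests.
#'
#' @param spec a [scene_spec()].
#' @param name,time_h passed to [render_stack()].
#' @return list with `stack`, `truth`, `cells` (the label volumes) and
#'   `particles`.
#' @export
simulate_scene <- function(spec, name = "synthetic", time_h = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    cells <- generate_cells(spec)
    particles <- place_particles(spec, cells$labels)
    rendered <- render_stack(spec, cells, particles, name = name,
                             time_h = time_h)
    list(stack = rendered$stack, truth = rendered$truth, cells = cells,
         particles = rendered$truth$particles)
  })
}

#' Read/write a ground-truth manifest
#'
#' @param truth manifest list as produced by [render_stack()].
#' @param path JSON file path.
#' @return `write_truth_manifest()` returns `path` invisibly;
#'   `read_truth_manifest()` returns the manifest list.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
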