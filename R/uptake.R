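#' Assign particles to cells by centroid position
#'
#' A particle belongs to the cell whose segmented volume contains its
#' centroid, treated as a dimensionless point: the physical centroid is
#' mapped back to a voxel index by flooring `centroid_um / spacing` per axis
#' and looked up in the cell label volume. Centroids falling on background
#' (label 0) — including particles sitting *on* a cell surface — are
#' classified as outside; no membrane-shell compartment is modeled.
#'
#' @param particles data frame of segmented particles (needs `object_id`,
#'   `cz_um`, `cy_um`, `cx_um`), as returned by [segment_objects()].
#' @param cell_labels integer 3D label array of segmented cells.
#' @param spacing a [voxel_spacing()].
#' @return data frame with columns `object_id`, `cell_id` (0 = outside) and
#'   `inside`.
#' @export
assign_particles <- function(particles, cell_labels, spacing) {
  spacing <- as_voxel_spacing(spacing)
  d <- dim(cell_labels)
  if (nrow(particles) == 0) {
    return(data.frame(object_id = integer(0), cell_id = integer(0),
                      inside = logical(0)))
  }
  vz <- floor(particles$cz_um / spacing[["dz"]])
  vy <- floor(particles$cy_um / spacing[["dy"]])
  vx <- floor(particles$cx_um / spacing[["dx"]])
  if (any(vz < 0 | vz >= d[1] | vy < 0 | vy >= d[2] | vx < 0 | vx >= d[3])) {
    stop("particle centroid outside the volume bounds")
  }
  lin <- 1 + vz + d[1] * (vy + d[2] * vx)
  cell_id <- as.integer(cell_labels[lin])
  data.frame(object_id = particles$object_id, cell_id = cell_id,
             inside = cell_id > 0L)
}

#' Per-cell uptake summary
#'
#' Counts the particles assigned to each cell and derives the two
#' concentration measures: per unit cell volume (um^-3) and per unit cell
#' surface (um^-2). Cells with no particles appear with zeros.
#'
#' @param assignment data frame from [assign_particles()].
#' @param cells data frame of segmented cells (needs `object_id`,
#'   `volume_um3`, `surface_um2`).
#' @return data frame with columns `cell_id`, `volume_um3`, `surface_um2`,
#'   `n_particles_inside`, `conc_per_um3`, `conc_per_um2`.
#' @export
summarize_cells <- function(assignment, cells) {
  inside <- assignment$cell_id[assignment$cell_id > 0L]
  if (length(inside) > 0 && !all(inside %in% cells$object_id)) {
    stop("assignment references cell ids absent from the cell table")
  }
  counts <- if (length(inside) > 0) {
    tabulate(inside, nbins = max(cells$object_id, inside))
  } else {
    integer(max(cells$object_id, 0))
  }
  n_in <- counts[cells$object_id]
  n_in[is.na(n_in)] <- 0L
  data.frame(
    cell_id = cells$object_id,
    volume_um3 = cells$volume_um3,
    surface_um2 = cells$surface_um2,
    n_particles_inside = n_in,
    conc_per_um3 = n_in / cells$volume_um3,
    conc_per_um2 = n_in / cells$surface_um2
  )
}

#' Field-of-view summary
#'
#' Totals over one image: all detected particles, those inside any cell, the
#' inside fraction (inside count normalized to the total particle count in
#' the field of view), the summed cell volume, and the pooled concentration
#' `n_inside_total / total_cell_volume_um3` — the headline quantity plotted
#' against incubation time.
#'
#' @param assignment data frame from [assign_particles()].
#' @param cell_records data frame from [summarize_cells()].
#' @return one-row data frame with columns `n_particles_total`,
#'   `n_inside_total`, `inside_fraction`, `total_cell_volume_um3`,
#'   `pooled_conc_per_um3`. With zero detected particles `inside_fraction`
#'   is `NA` (missing, not 0) and a warning is raised.
#' @export
summarize_fov <- function(assignment, cell_records) {
  n_total <- nrow(assignment)
  n_inside <- sum(assignment$cell_id > 0L)
  stopifnot(n_inside == sum(cell_records$n_particles_inside))
  total_vol <- sum(cell_records$volume_um3)
  if (n_total == 0) {
    warning("no particles detected: inside_fraction is undefined")
  }
  data.frame(
    n_particles_total = n_total,
    n_inside_total = n_inside,
    inside_fraction = if (n_total > 0) n_inside / n_total else NA_real_,
    total_cell_volume_um3 = total_vol,
    pooled_conc_per_um3 = if (total_vol > 0) n_inside / total_vol else NA_real_
  )
}

#' Bin replicate images into nominal time points
#'
#' Confocal acquisition is slow (~20 min per stack), so replicates of a
#' nominal incubation time are acquired in a window around it; e.g. images
#' started at 40, 60 and 80 min all represent the 1 h point. Each image is
#' assigned to the bin whose center is nearest within `bin_halfwidth_h`
#' (ties to the earlier center); per bin the mean and the *population*
#' standard deviation (divisor n, the convention used for the error bars)
#' of the pooled concentration are reported.
#'
#' @param images data frame with one row per image: columns `time_h`
#'   (acquisition time in hours) and `pooled_conc_per_um3`.
#' @param bin_centers_h bin centers in hours (default 1..8 h, hourly
#'   sampling).
#' @param bin_halfwidth_h half-width of each bin in hours (default 0.5).
#' @return data frame with columns `time_h`, `n_images`,
#'   `mean_conc_per_um3`, `sd_conc_per_um3`, one row per non-empty bin.
#'   Images falling outside every bin are returned in the `unbinned`
#'   attribute and flagged with a warning.
#' @export
bin_time_points <- function(images, bin_centers_h = 1:8,
                            bin_halfwidth_h = 0.5) {
  stopifnot(all(c("time_h", "pooled_conc_per_um3") %in% names(images)))
  centers <- sort(as.numeric(bin_centers_h))
  if (length(centers) > 1 && any(diff(centers) < 2 * bin_halfwidth_h)) {
    stop("bins overlap: centers must be at least 2 * halfwidth apart")
  }
  dist <- abs(outer(images$time_h, centers, `-`))
  nearest <- apply(dist, 1, which.min)      # earliest center wins ties
  in_bin <- dist[cbind(seq_len(nrow(images)), nearest)] <= bin_halfwidth_h
  if (any(!in_bin)) {
    warning(sum(!in_bin), " image(s) fall outside every bin; see attr ",
            "'unbinned'")
  }
  binned <- images[in_bin, , drop = FALSE]
  bin_of <- centers[nearest[in_bin]]
  stats <- lapply(split(binned$pooled_conc_per_um3, bin_of), function(v) {
    m <- mean(v)
    c(n = length(v), mean = m, sd = sqrt(mean((v - m)^2)))
  })
  out <- data.frame(
    time_h = as.numeric(names(stats)),
    n_images = vapply(stats, `[[`, numeric(1), "n"),
    mean_conc_per_um3 = vapply(stats, `[[`, numeric(1), "mean"),
    sd_conc_per_um3 = vapply(stats, `[[`, numeric(1), "sd"),
    row.names = NULL
  )
  out <- out[order(out$time_h), , drop = FALSE]
  attr(out, "unbinned") <- images[!in_bin, , drop = FALSE]
  out
}
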