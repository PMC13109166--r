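#' Read and validate a run configuration
#'
#' The YAML configuration drives [run_pipeline()]. Recognized keys:
#' `inputs` (list of `{path, time_h}`), `role_map` (role -> channel index),
#' `spacing` (`{dz, dy, dx}` in um, or the string `"from_metadata"`),
#' `particle` and `cell` blocks (each with `sigma_vox`, `threshold`
#' (`auto` or a number), `min_voxels`, `max_voxels`, `connectivity`,
#' `exclude_edge_objects`; the cell block also takes `channel`, one of
#' `cellbody`/`membrane`), `bins` (`centers_h`, `halfwidth_h`),
#' `aggregation` (`k_max`, `seed`, `mode` = `weights` or `areas`) and
#' `out_dir`. Validation is fail-fast: every referenced input file must
#' exist before any computation starts.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return a validated `run_config` list (with defaults filled in).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: '", path, "'")
    y <- yaml::read_yaml(path)
    y$config_hash <- unname(tools::md5sum(path))
    y
  } else {
    as.list(path)
  }
  if (is.null(cfg$inputs) || length(cfg$inputs) == 0) {
    stop("config declares no inputs")
  }
  for (inp in cfg$inputs) {
    if (is.null(inp$path)) stop("every input needs a 'path'")
    if (!file.exists(inp$path)) {
      stop("input file not found: '", inp$path, "'")
    }
  }
  if (is.null(cfg$role_map)) {
    cfg$role_map <- c(reflection = 1, cellbody = 2, membrane = 3)
  }
  cfg$role_map <- unlist(cfg$role_map)
  defaults <- function(block, min_voxels) {
    b <- if (is.null(block)) list() else block
    b$sigma_vox <- b$sigma_vox %||% 1
    b$threshold <- b$threshold %||% "auto"
    b$min_voxels <- b$min_voxels %||% min_voxels
    b$max_voxels <- b$max_voxels %||% Inf
    b$connectivity <- b$connectivity %||% 26
    b$exclude_edge_objects <- b$exclude_edge_objects %||% FALSE
    b
  }
  # protocol defaults: size filter 0 for particles, 1000 voxels for cells
  cfg$particle <- defaults(cfg$particle, 0)
  cfg$cell <- defaults(cfg$cell, 1000)
  cfg$cell$channel <- cfg$cell$channel %||% "cellbody"
  if (!cfg$cell$channel %in% c("cellbody", "membrane")) {
    stop("cell$channel must be 'cellbody' or 'membrane'")
  }
  cfg$bins <- cfg$bins %||% list()
  cfg$bins$centers_h <- cfg$bins$centers_h %||% 1:8
  cfg$bins$halfwidth_h <- cfg$bins$halfwidth_h %||% 0.5
  cfg$aggregation <- cfg$aggregation %||% list()
  cfg$aggregation$k_max <- cfg$aggregation$k_max %||% 4
  cfg$aggregation$seed <- cfg$aggregation$seed %||% 1
  cfg$aggregation$mode <- cfg$aggregation$mode %||% "weights"
  cfg$out_dir <- cfg$out_dir %||% "npuptake_results"
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seg_params_from <- function(block) {
  segmentation_params(
    threshold = if (identical(block$threshold, "auto")) "auto" else
      as.numeric(block$threshold),
    min_voxels = block$min_voxels, max_voxels = block$max_voxels,
    exclude_edge_objects = block$exclude_edge_objects,
    connectivity = block$connectivity
  )
}

#' Run the full uptake pipeline over one or more stacks
#'
#' For each input stack: segment particles on the reflection channel and
#' cells on the configured fluorescence channel, assign particles to cells
#' by centroid, and summarize. Per image, `particles.csv`, `cells.csv` and
#' `fov_summary.csv` are written under `out_dir/<image name>/`. Across
#' images, `timeprofile.csv` (replicates binned to nominal time points),
#' `aggregation.csv` and `intensity_volume.csv` (pooled particle
#' intensities) are written under `out_dir/`, together with
#' `run_metadata.json` recording the resolved segmentation thresholds per
#' image, all parameters, seed and software version. Outputs are
#' deterministic: identical config and inputs give byte-identical files.
#'
#' @param config a config path or [read_run_config()] result.
#' @param verbose print one progress line per stage and image.
#' @return (invisibly) list with `images` (per-image results), `timeprofile`,
#'   `aggregation`, `intensity_volume` and `metadata`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))

  spacing_override <- if (is.null(cfg$spacing) ||
                          identical(cfg$spacing, "from_metadata")) NULL else
    as_voxel_spacing(cfg$spacing)

  images <- list()
  fov_rows <- list()
  particle_pool <- list()
  thresholds <- list()

  for (i in seq_along(cfg$inputs)) {
    inp <- cfg$inputs[[i]]
    img_name <- tools::file_path_sans_ext(basename(inp$path))
    stack <- tryCatch(
      read_stack(inp$path, cfg$role_map, spacing_override,
                 time_h = inp$time_h),
      error = function(e) stop("stage read_stack failed on '", inp$path,
                               "': ", conditionMessage(e))
    )
    say("[read] %s: %s", img_name,
        paste(dim(stack$data), collapse = "x"))

    particles <- tryCatch(
      segment_objects(get_channel(stack, "reflection"),
                      filter_params(cfg$particle$sigma_vox),
                      seg_params_from(cfg$particle), stack$spacing),
      error = function(e) stop("stage segment_particles failed on '",
                               img_name, "': ", conditionMessage(e))
    )
    say("[particles] %s: %d objects (threshold %.4g)", img_name,
        nrow(particles), attr(particles, "threshold"))

    cells <- tryCatch(
      segment_objects(get_channel(stack, cfg$cell$channel),
                      filter_params(cfg$cell$sigma_vox),
                      seg_params_from(cfg$cell), stack$spacing),
      error = function(e) stop("stage segment_cells failed on '", img_name,
                               "': ", conditionMessage(e))
    )
    say("[cells] %s: %d objects (threshold %.4g)", img_name, nrow(cells),
        attr(cells, "threshold"))

    cell_labels <- attr(cells, "labels")
    # mask labels down to the cells that survived the size/edge filters
    keep <- array(cell_labels %in% cells$object_id, dim(cell_labels))
    cell_labels[!keep] <- 0L

    assignment <- assign_particles(particles, cell_labels, stack$spacing)
    cell_records <- summarize_cells(assignment, cells)
    fov <- summarize_fov(assignment, cell_records)
    say("[assign] %s: %d/%d particles inside cells", img_name,
        fov$n_inside_total, fov$n_particles_total)

    img_dir <- file.path(cfg$out_dir, img_name)
    write_results(
      list(particles = particles, cells = cell_records, fov_summary = fov),
      img_dir
    )
    thresholds[[img_name]] <- list(
      particle_threshold = as.numeric(attr(particles, "threshold")),
      cell_threshold = as.numeric(attr(cells, "threshold"))
    )
    fov$time_h <- inp$time_h %||% stack$time_h %||% NA_real_
    fov_rows[[i]] <- fov
    particle_pool[[i]] <- particles
    images[[img_name]] <- list(particles = particles, cells = cell_records,
                               fov = fov, assignment = assignment)
  }

  fov_all <- do.call(rbind, fov_rows)
  timeprofile <- if (all(is.finite(fov_all$time_h))) {
    bin_time_points(fov_all, cfg$bins$centers_h, cfg$bins$halfwidth_h)
  } else {
    data.frame(time_h = numeric(0), n_images = numeric(0),
               mean_conc_per_um3 = numeric(0), sd_conc_per_um3 = numeric(0))
  }

  pooled <- do.call(rbind, particle_pool)
  aggregation <- NULL
  iv <- NULL
  if (nrow(pooled) >= 10) {
    fit <- fit_multiplicity_mixture(pooled$integrated_density,
                                    K_max = cfg$aggregation$k_max,
                                    seed = cfg$aggregation$seed)
    fr <- if (identical(cfg$aggregation$mode, "areas")) area_fractions(fit)
          else fit$fractions_pct
    aggregation <- as.data.frame(c(
      list(K = fit$K, mu1 = fit$mu1, bic = fit$bic,
           n_objects = fit$n_objects),
      setNames(as.list(fr), paste0("fraction_pct_", seq_len(fit$K))),
      setNames(as.list(fit$sigmas), paste0("sigma_", seq_len(fit$K)))
    ))
    say("[aggregate] K=%d, mu1=%.4g, fractions %s", fit$K, fit$mu1,
        paste(sprintf("%.1f%%", fr), collapse = "/"))
  }
  if (nrow(pooled) >= 3 && length(unique(pooled$volume_um3)) >= 2) {
    iv <- as.data.frame(fit_intensity_volume(pooled))
  }

  metadata <- list(
    config_hash = cfg$config_hash %||% NA,
    seed = cfg$aggregation$seed,
    thresholds = thresholds,
    parameters = cfg[c("role_map", "particle", "cell", "bins",
                       "aggregation")],
    inputs = vapply(cfg$inputs, function(i) i$path, character(1))
  )
  tables <- list(timeprofile = timeprofile)
  if (!is.null(aggregation)) tables$aggregation <- aggregation
  if (!is.null(iv)) tables$intensity_volume <- iv
  write_results(tables, cfg$out_dir, metadata)

  invisible(list(images = images, timeprofile = timeprofile,
                 aggregation = aggregation, intensity_volume = iv,
                 metadata = metadata))
}
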