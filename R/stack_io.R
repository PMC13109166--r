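#' Multichannel 3D stack
#'
#' Container for one confocal acquisition: a 4D intensity array indexed
#' `[channel, z, y, x]`, the physical voxel spacing, and a mapping from
#' channel roles to channel indices. The three roles mirror a typical
#' label-free uptake acquisition: `reflection` (back-scattered light from the
#' nanoparticles), `cellbody` (whole-cell fluorescence, e.g. cytosolic GFP)
#' and `membrane` (a membrane stain). Intensities are on a nominal 16-bit
#' scale, i.e. within \[0, 65535\].
#'
#' @param data numeric array with `dim = c(n_channels, nz, ny, nx)`.
#' @param spacing a [voxel_spacing()] (um per voxel along z, y, x).
#' @param roles named integer vector mapping role names (any of
#'   `"reflection"`, `"cellbody"`, `"membrane"`) to 1-based channel indices.
#' @param name free-text identifier for the acquisition.
#' @param time_h optional nominal incubation time in hours.
#' @return an object of class `multichannel_stack`.
#' @seealso [read_stack()], [write_stack()], [get_channel()]
#' @export
multichannel_stack <- function(data, spacing, roles, name = "stack",
                               time_h = NULL) {
  spacing <- as_voxel_spacing(spacing)
  if (!is.array(data) || length(dim(data)) != 4) {
    stop("data must be a 4D array [channel, z, y, x]")
  }
  if (any(dim(data) < 1)) stop("all extents must be >= 1")
  roles <- validate_roles(roles, dim(data)[1])
  rng <- range(data)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 65535) {
    stop("intensities must be finite and within [0, 65535] (16-bit scale)")
  }
  structure(
    list(data = data, spacing = spacing, roles = roles,
         name = as.character(name),
         time_h = if (is.null(time_h)) NULL else as.numeric(time_h)),
    class = "multichannel_stack"
  )
}

validate_roles <- function(roles, n_channels) {
  allowed <- c("reflection", "cellbody", "membrane")
  if (length(roles) < 1) stop("at least one channel role must be declared")
  idx <- as.integer(unlist(roles))
  nm <- names(roles)
  if (is.null(nm) || any(nm == "")) stop("roles must be a named vector/list")
  bad <- setdiff(nm, allowed)
  if (length(bad) > 0) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(nm)) stop("each role maps to exactly one channel")
  if (any(is.na(idx)) || any(idx < 1) || any(idx > n_channels)) {
    stop("role_map references a channel index outside 1..", n_channels)
  }
  setNames(idx, nm)
}

#' @export
print.multichannel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multichannel_stack '%s': %d channel(s), %d x %d x %d (z,y,x)\n",
              x$name, d[1], d[2], d[3], d[4]))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(x$roles), x$roles), collapse = ", ")))
  print(x$spacing)
  if (!is.null(x$time_h)) cat(sprintf("  incubation time: %g h\n", x$time_h))
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack a [multichannel_stack()].
#' @param role a role name present in `stack$roles`, or an integer channel
#'   index.
#' @return a 3D numeric array with `dim = c(nz, ny, nx)`.
#' @export
get_channel <- function(stack, role) {
  stopifnot(inherits(stack, "multichannel_stack"))
  idx <- if (is.character(role)) {
    if (!role %in% names(stack$roles)) {
      stop("role '", role, "' is not declared for this stack")
    }
    stack$roles[[role]]
  } else {
    as.integer(role)
  }
  d <- dim(stack$data)
  if (idx < 1 || idx > d[1]) stop("channel index out of range")
  arr <- stack$data[idx, , , , drop = FALSE]
  dim(arr) <- d[2:4]
  arr
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multichannel stack to disk
#'
#' Writes a multi-page 16-bit grayscale TIFF (pages ordered channel-fastest,
#' then z) together with a JSON sidecar `<path>.json` holding the voxel
#' spacing, channel roles, name and incubation time. Intensities must be
#' integer-valued within \[0, 65535\]; the round trip
#' `read_stack(write_stack(s))` then reproduces the data bit-exactly and the
#' spacing to 1e-6 um.
#'
#' @param stack a [multichannel_stack()] with integer-valued intensities.
#' @param path output file path (e.g. `"scene.tif"`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "multichannel_stack"))
  if (any(stack$data != round(stack$data))) {
    stop("stack intensities must be integer-valued for lossless 16-bit output")
  }
  d <- dim(stack$data)
  pages <- vector("list", d[1] * d[2])
  p <- 0L
  for (zi in seq_len(d[2])) {
    for (ci in seq_len(d[1])) {
      p <- p + 1L
      page <- stack$data[ci, zi, , ]
      dim(page) <- d[3:4]
      pages[[p]] <- page / 65535
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = 16,
                    compression = "deflate"),
    error = function(e) stop("cannot write TIFF at '", path, "': ",
                             conditionMessage(e))
  )
  meta <- list(
    format = "npuptake-stack",
    n_channels = d[1], nz = d[2], ny = d[3], nx = d[4],
    spacing_um = list(dz = stack$spacing[["dz"]], dy = stack$spacing[["dy"]],
                      dx = stack$spacing[["dx"]]),
    roles = as.list(stack$roles),
    name = stack$name,
    time_h = stack$time_h,
    page_order = "channel_fastest"
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multichannel 3D stack from a TIFF file
#'
#' Reads a multi-page (or OME) TIFF and normalizes it to the package's
#' `[channel, z, y, x]` layout. The channel/z geometry and voxel spacing are
#' resolved, in order of precedence, from: a JSON sidecar written by
#' [write_stack()]; an ImageJ-style hyperstack description tag
#' (`channels=`/`slices=`/`spacing=`); an OME-XML description tag (`SizeC`,
#' `SizeZ`, `PhysicalSize*`, requires the xml2 package). If none resolves a
#' channel axis the file is treated as single-channel only when the role map
#' declares a single role; otherwise reading fails. Spacing not present in
#' any metadata source must be supplied via `spacing_override`; concentrations
#' in um^-3 would be meaningless with a guessed spacing, so there is no
#' default.
#'
#' @param path TIFF file path.
#' @param role_map named vector/list mapping roles to 1-based channel indices.
#' @param spacing_override optional [voxel_spacing()]; when given it takes
#'   precedence over any embedded or sidecar spacing.
#' @param name optional identifier (defaults to the file name).
#' @param time_h optional incubation time in hours (overrides sidecar).
#' @return a [multichannel_stack()]. Intensities are returned unmodified on
#'   the 16-bit scale.
#' @export
read_stack <- function(path, role_map, spacing_override = NULL,
                       name = NULL, time_h = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  meta <- resolve_stack_metadata(path, pages, n_pages, n_roles = length(role_map))

  if (!is.null(spacing_override)) {
    spacing <- as_voxel_spacing(spacing_override)
  } else if (!is.null(meta$spacing)) {
    spacing <- as_voxel_spacing(meta$spacing)
  } else {
    stop("no voxel spacing in file metadata; pass spacing_override ",
         "(guessed spacing would corrupt all physical quantities)")
  }

  nc <- meta$n_channels
  nz <- meta$nz
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nc, nz, ny, nx))
  p <- 0L
  for (zi in seq_len(nz)) {
    for (ci in seq_len(nc)) {
      p <- p + 1L
      data[ci, zi, , ] <- pages[[p]]
    }
  }
  multichannel_stack(
    data, spacing, role_map,
    name = if (!is.null(name)) name else
      if (!is.null(meta$name)) meta$name else basename(path),
    time_h = if (!is.null(time_h)) time_h else meta$time_h
  )
}

resolve_stack_metadata <- function(path, pages, n_pages, n_roles) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    m <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (identical(m$format, "npuptake-stack")) {
      if (m$n_channels * m$nz != n_pages) {
        stop("sidecar geometry (", m$n_channels, " x ", m$nz,
             ") does not match the ", n_pages, " TIFF pages")
      }
      return(list(n_channels = m$n_channels, nz = m$nz,
                  spacing = m$spacing_um, name = m$name,
                  time_h = m$time_h))
    }
  }
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && grepl("ImageJ", desc, fixed = TRUE)) {
    m <- parse_imagej_description(desc, n_pages)
    if (!is.null(m)) return(m)
  }
  if (!is.null(desc) && grepl("<OME", desc, fixed = TRUE) &&
      requireNamespace("xml2", quietly = TRUE)) {
    m <- parse_ome_description(desc, n_pages)
    if (!is.null(m)) return(m)
  }
  if (n_roles == 1) {
    return(list(n_channels = 1L, nz = n_pages, spacing = NULL,
                name = NULL, time_h = NULL))
  }
  stop("cannot resolve a channel axis for '", path, "': no sidecar, ",
       "ImageJ or OME metadata found and more than one role requested")
}

ij_field <- function(desc, key) {
  m <- regmatches(desc, regexec(paste0(key, "=([0-9.eE+-]+)"), desc))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else NULL
}

parse_imagej_description <- function(desc, n_pages) {
  ch <- ij_field(desc, "channels")
  sl <- ij_field(desc, "slices")
  if (is.null(ch)) ch <- 1
  if (is.null(sl)) sl <- n_pages / ch
  if (ch * sl != n_pages) return(NULL)
  dz <- ij_field(desc, "spacing")
  list(n_channels = as.integer(ch), nz = as.integer(sl),
       spacing = if (is.null(dz)) NULL else c(dz = dz, dy = NA, dx = NA),
       name = NULL, time_h = NULL)
}

parse_ome_description <- function(desc, n_pages) {
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  num_attr <- function(a) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) NULL else as.numeric(v)
  }
  ch <- num_attr("SizeC"); sl <- num_attr("SizeZ")
  if (is.null(ch) || is.null(sl) || ch * sl != n_pages) return(NULL)
  dz <- num_attr("PhysicalSizeZ")
  dy <- num_attr("PhysicalSizeY")
  dx <- num_attr("PhysicalSizeX")
  spacing <- if (!is.null(dz) && !is.null(dy) && !is.null(dx)) {
    c(dz = dz, dy = dy, dx = dx)
  } else NULL
  list(n_channels = as.integer(ch), nz = as.integer(sl), spacing = spacing,
       name = NULL, time_h = NULL)
}

# fixed, documented column orders for the CSV result tables
RESULT_COLUMNS <- list(
  particles = c("object_id", "cz_um", "cy_um", "cx_um", "voxel_count",
                "volume_um3", "surface_um2", "integrated_density",
                "touches_edge"),
  cells = c("cell_id", "volume_um3", "surface_um2", "n_particles_inside",
            "conc_per_um3", "conc_per_um2"),
  fov_summary = c("n_particles_total", "n_inside_total", "inside_fraction",
                  "total_cell_volume_um3", "pooled_conc_per_um3"),
  timeprofile = c("time_h", "n_images", "mean_conc_per_um3",
                  "sd_conc_per_um3"),
  intensity_volume = c("slope", "intercept", "r_squared")
)

#' Write result tables and run metadata
#'
#' Serializes the pipeline's tabular results as CSV files with a fixed,
#' documented column order (UTF-8, comma separator, `.` decimal point) and a
#' single `run_metadata.json`. Serialization is deterministic: identical
#' inputs produce byte-identical files.
#'
#' @param tables named list of data frames; recognized names are
#'   `particles`, `cells`, `fov_summary`, `timeprofile`, `aggregation`,
#'   `intensity_volume`. Unrecognized names are written with their columns
#'   as-is.
#' @param path output directory (created if missing).
#' @param metadata named list stored as `run_metadata.json` (e.g. config
#'   hash, seed, resolved thresholds). The package version is always added.
#' @return character vector of files written.
#' @export
write_results <- function(tables, path, metadata = list()) {
  stopifnot(is.list(tables))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  written <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    want <- RESULT_COLUMNS[[nm]]
    if (!is.null(want)) {
      missing <- setdiff(want, names(tab))
      if (length(missing) > 0) {
        stop("table '", nm, "' lacks required column(s): ",
             paste(missing, collapse = ", "))
      }
      tab <- tab[, want, drop = FALSE]
    }
    f <- file.path(path, paste0(nm, ".csv"))
    write.csv(tab, f, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    written <- c(written, f)
  }
  metadata$software_version <- as.character(packageVersion("npuptake"))
  mf <- file.path(path, "run_metadata.json")
  jsonlite::write_json(metadata, mf, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  c(written, mf)
}
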