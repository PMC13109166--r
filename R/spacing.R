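#' Voxel spacing
#'
#' Physical size of one voxel along each axis, in micrometres. Confocal
#' stacks are anisotropic: the z-step (here typically ~0.3 um) is several
#' times the lateral pixel size (~0.05-0.07 um).
#'
#' @param dz,dy,dx spacing in um along z (between layers), y (rows) and x
#'   (columns); all strictly positive.
#' @return an object of class `voxel_spacing`: a named numeric vector
#'   `c(dz, dy, dx)`.
#' @examples
#' sp <- voxel_spacing(0.3, 0.06, 0.06)
#' voxel_volume(sp)  # um^3 per voxel
#' @export
voxel_spacing <- function(dz, dy, dx) {
  s <- c(dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("voxel spacing must be finite and strictly positive on all axes")
  }
  structure(s, class = "voxel_spacing")
}

#' @rdname voxel_spacing
#' @param spacing a `voxel_spacing`
#' @export
voxel_volume <- function(spacing) {
  spacing <- as_voxel_spacing(spacing)
  unname(prod(spacing))
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing (um): dz=%g dy=%g dx=%g (volume %g um^3)\n",
              x[["dz"]], x[["dy"]], x[["dx"]], prod(x)))
  invisible(x)
}

as_voxel_spacing <- function(x) {
  if (inherits(x, "voxel_spacing")) return(x)
  x <- unlist(x)
  if (length(x) != 3) stop("spacing must have 3 elements (dz, dy, dx)")
  if (is.null(names(x)) || !all(c("dz", "dy", "dx") %in% names(x))) {
    names(x) <- c("dz", "dy", "dx")
  }
  voxel_spacing(x[["dz"]], x[["dy"]], x[["dx"]])
}

# physical coordinates of voxel centers: (index + 0.5) * spacing, 0-based
vox_to_um <- function(idx0, spacing) {
  sweep(idx0 + 0.5, 2, as.numeric(spacing), `*`)
}
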