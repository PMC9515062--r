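#' 3-D medical volume
#'
#' A scalar voxel grid with world geometry: per-axis spacing (mm), origin
#' (mm) and a 3x3 orthonormal direction matrix whose columns are the world
#' directions of the voxel axes. The world frame is LPS (DICOM patient
#' convention); readers of RAS data (NIfTI) flip axes on input. Voxel
#' indices are 0-based and continuous, and the world position of index
#' (0, 0, 0) is the *center* of the first voxel (DICOM convention), so
#' `world = origin + direction %*% (index * spacing)`.
#'
#' @param voxels 3-D numeric array (x fastest, like the on-disk order of all
#'   supported formats).
#' @param spacing length-3 positive numeric, mm.
#' @param origin length-3 numeric, mm (center of voxel (0,0,0)).
#' @param direction 3x3 orthonormal matrix (columns = axis directions).
#' @param modality `"CT"`, `"MRI"` or `"unknown"`; a hint only, carried
#'   through to detection defaults.
#' @return An object of class `med_volume`.
#' @export
med_volume <- function(voxels, spacing, origin = c(0, 0, 0), direction = diag(3),
                       modality = c("unknown", "CT", "MRI")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L || length(voxels) == 0L)
    stop("voxels must be a non-empty 3-D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  direction <- unname(as.matrix(direction))
  stopifnot(length(spacing) == 3L, length(origin) == 3L,
            identical(dim(direction), c(3L, 3L)))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive in all three axes")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix is not orthonormal")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 direction = direction, modality = modality),
            class = "med_volume")
}

#' @export
print.med_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Medical volume (%s): %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel/world coordinate conversion
#'
#' Maps 0-based continuous voxel indices to world coordinates (mm, LPS) and
#' back. Points outside the grid are allowed; the two functions compose to
#' the identity to numerical precision.
#'
#' @param volume a [med_volume()].
#' @param index,point length-3 vector or n x 3 matrix.
#' @return Same shape as the input.
#' @export
voxel_to_world <- function(volume, index) {
  stopifnot(inherits(volume, "med_volume"))
  vec <- is.null(dim(index))
  idx <- if (vec) matrix(as.numeric(index), 1L) else as.matrix(index)
  out <- sweep(idx, 2L, volume$spacing, "*") %*% t(volume$direction)
  out <- sweep(out, 2L, volume$origin, "+")
  if (vec) drop(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, point) {
  stopifnot(inherits(volume, "med_volume"))
  vec <- is.null(dim(point))
  p <- if (vec) matrix(as.numeric(point), 1L) else as.matrix(point)
  out <- sweep(p, 2L, volume$origin, "-") %*% volume$direction
  out <- sweep(out, 2L, volume$spacing, "/")
  if (vec) drop(out) else out
}

#' Voxel size helpers
#'
#' `voxel_volume()` is the physical volume of one voxel (mm^3);
#' `voxel_diagonal()` the length of its space diagonal (mm), the natural
#' scale for centroid-accuracy statements on anisotropic grids.
#'
#' @param volume a [med_volume()] (or length-3 spacing vector).
#' @return A scalar, mm^3 respectively mm.
#' @export
voxel_volume <- function(volume) {
  s <- if (inherits(volume, "med_volume")) volume$spacing else as.numeric(volume)
  prod(s)
}

#' @rdname voxel_volume
#' @export
voxel_diagonal <- function(volume) {
  s <- if (inherits(volume, "med_volume")) volume$spacing else as.numeric(volume)
  sqrt(sum(s^2))
}
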