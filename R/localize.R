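#' Localize the fiducial marker in a volume
#'
#' The central fit of the package: reduces the volume to bright-sphere
#' candidate features ([detect_candidates()]), establishes the
#' candidate-to-feature correspondence from the marker's unique pairwise
#' distance configuration ([match_candidates_to_geometry()]) and estimates
#' the rigid marker-to-image transform with Horn's closed-form method
#' ([horn_absolute_orientation()]). The run is deterministic, and the
#' returned object carries full provenance: every chosen threshold,
#' per-stage candidate count, the correspondence and the fiducial
#' registration error (FRE).
#'
#' Failures are reported as a status, never as a silently wrong pose:
#' `"insufficient_candidates"` (fewer than eight plausible features, e.g.
#' an air-only volume), `"no_consistent_subset"` (no eight candidates
#' reproduce the distance configuration within tolerance) or
#' `"high_residual"` (a correspondence exists but its FRE exceeds the
#' acceptance threshold).
#'
#' @param volume a [med_volume()].
#' @param geometry a [marker_geometry()], e.g. `marker_geometry("3_15")`.
#' @param profile a [modality_profile()]; defaults to the geometry's
#'   modality.
#' @param percentile background-suppression percentile, see
#'   [suppress_background()].
#' @param tau distance-match tolerance, mm. Default
#'   `max(1, 0.75 * max(spacing))`: centroid error scales with the slice
#'   thickness.
#' @param fre_threshold Horn-fit acceptance residual, mm. Default
#'   `max(1, voxel diagonal)`.
#' @param max_candidates,max_exhaustive see [binarize_and_label()] and
#'   [match_candidates_to_geometry()].
#' @param verbose print per-stage candidate counts.
#' @return An object of class `marker_localization`: a list with
#'   `transform` (marker to image, mm, LPS), `correspondences` (data frame
#'   with feature index, candidate label, detected world/voxel centroids,
#'   fitted positions and residuals), `fre`, `status`, `candidates`,
#'   `params`, `geometry`, `volume_info` and `call`. Methods: `print`,
#'   `summary`, `coef` (4x4 homogeneous matrix), `predict` (map marker-frame
#'   points to image coordinates), `fitted`, `residuals`, `plot`.
#' @examples
#' geo <- marker_geometry("3_15")
#' scene <- render_marker_volume(geo, rigid_transform(), render_profile(noise_sd = 0),
#'                               spacing = c(0.98, 0.98, 3))
#' fit <- localize_marker(scene$volume, geo)
#' fit
#' coef(fit)
#' @export
localize_marker <- function(volume, geometry,
                            profile = modality_profile(geometry$modality),
                            percentile = 0.995,
                            tau = NULL, fre_threshold = NULL,
                            max_candidates = 500L, max_exhaustive = 16L,
                            verbose = FALSE) {
  stopifnot(inherits(volume, "med_volume"), inherits(geometry, "marker_geometry"))
  if (is.null(tau)) tau <- max(1, 0.75 * max(volume$spacing))
  if (is.null(fre_threshold)) fre_threshold <- max(1, voxel_diagonal(volume))
  cand <- detect_candidates(volume, geometry, profile,
                            percentile = percentile,
                            max_candidates = max_candidates, verbose = verbose)
  m <- match_candidates_to_geometry(cand, geometry, tau = tau,
                                    fre_threshold = fre_threshold,
                                    max_exhaustive = max_exhaustive)
  params <- c(attr(cand, "counts"),
              list(percentile = percentile, tau = tau,
                   fre_threshold = fre_threshold,
                   max_candidates = max_candidates,
                   max_exhaustive = max_exhaustive))
  out <- structure(list(
    status = m$status,
    transform = m$transform,
    fre = m$fre,
    correspondences = NULL,
    candidates = cand,
    params = params,
    geometry = geometry,
    volume_info = list(dim = dim(volume$voxels), spacing = volume$spacing,
                       origin = volume$origin, direction = volume$direction,
                       voxel_diagonal = voxel_diagonal(volume)),
    matching_stage = m$stage,
    call = match.call()
  ), class = "marker_localization")
  if (m$status == "success") {
    sel <- cand[m$selected, , drop = FALSE]
    fitted_pts <- transform_points(m$transform, geometry$centroids)
    out$correspondences <- data.frame(
      feature = 1:8,
      label_id = sel$label_id,
      x = sel$x, y = sel$y, z = sel$z,
      voxel_x = sel$voxel_x, voxel_y = sel$voxel_y, voxel_z = sel$voxel_z,
      fitted_x = fitted_pts[, 1], fitted_y = fitted_pts[, 2],
      fitted_z = fitted_pts[, 3],
      residual = m$residuals)
  }
  out
}

#' @export
print.marker_localization <- function(x, ...) {
  cat("Fiducial marker localization (", x$geometry$config_id, ", ",
      x$geometry$modality, ")\n", sep = "")
  if (x$status == "success") {
    cat(sprintf("  status: success (%s matching), FRE %.4f mm\n",
                x$matching_stage, x$fre))
    e <- to_euler_angles(x$transform)
    cat(sprintf("  translation (%.2f, %.2f, %.2f) mm, Euler z-y-x (%.2f, %.2f, %.2f) deg\n",
                x$transform$translation[1], x$transform$translation[2],
                x$transform$translation[3], e[1], e[2], e[3]))
  } else {
    cat("  status:", x$status,
        if (!is.null(x$fre)) sprintf("(best FRE %.3f mm)", x$fre) else "", "\n")
  }
  invisible(x)
}

#' @export
summary.marker_localization <- function(object, ...) {
  structure(list(fit = object), class = "summary.marker_localization")
}

#' @export
print.summary.marker_localization <- function(x, ...) {
  f <- x$fit
  print(f)
  p <- f$params
  cat(sprintf("  detection: threshold %.4g (percentile %.3f), %d components, %d candidates after pruning\n",
              p$threshold, p$percentile, p$n_components, p$n_final))
  cat(sprintf("  matching: tau %.2f mm, FRE threshold %.2f mm\n", p$tau, p$fre_threshold))
  if (f$status == "success") {
    cat("  per-feature residuals (mm):\n")
    print(round(stats::setNames(f$correspondences$residual,
                                paste0("f", f$correspondences$feature)), 4))
  }
  invisible(x)
}

#' @export
coef.marker_localization <- function(object, ...) {
  if (object$status != "success")
    stop("no pose estimated (status: ", object$status, ")")
  as.matrix(object$transform)
}

#' @export
predict.marker_localization <- function(object, newdata = NULL, ...) {
  if (object$status != "success")
    stop("no pose estimated (status: ", object$status, ")")
  if (is.null(newdata)) return(fitted(object))
  transform_points(object$transform, newdata)
}

#' @export
fitted.marker_localization <- function(object, ...) {
  if (object$status != "success")
    stop("no pose estimated (status: ", object$status, ")")
  transform_points(object$transform, object$geometry$centroids)
}

#' @export
residuals.marker_localization <- function(object, type = c("norm", "vector"), ...) {
  type <- match.arg(type)
  if (object$status != "success")
    stop("no pose estimated (status: ", object$status, ")")
  co <- object$correspondences
  if (type == "norm") return(stats::setNames(co$residual, paste0("f", co$feature)))
  cbind(x = co$x - co$fitted_x, y = co$y - co$fitted_y, z = co$z - co$fitted_z)
}

#' @export
plot.marker_localization <- function(x, ...) {
  cand <- x$candidates
  planes <- list(c("x", "y"), c("x", "z"), c("y", "z"))
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (pl in planes) {
    graphics::plot(cand[[pl[1]]], cand[[pl[2]]], pch = 1, col = "grey40",
                   xlab = paste(pl[1], "(mm)"), ylab = paste(pl[2], "(mm)"),
                   main = paste(pl[1], "-", pl[2]), asp = 1, ...)
    if (x$status == "success") {
      co <- x$correspondences
      graphics::points(co[[paste0("fitted_", pl[1])]], co[[paste0("fitted_", pl[2])]],
                       pch = 3, col = "red")
      graphics::text(co[[pl[1]]], co[[pl[2]]], labels = co$feature, pos = 3, cex = 0.7)
    }
  }
  invisible(x)
}
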