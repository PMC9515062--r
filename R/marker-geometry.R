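#' Marker geometry
#'
#' The fiducial marker carries eight spherical features distributed over two
#' parallel planes, four per plane, such that every feature has a unique
#' pairwise-distance configuration to the others. Configurations are named
#' `<diameter>_<min distance>`: the number before the underscore is the
#' feature diameter in mm (3 | 5 | 6), the number after it the minimum
#' centroid-to-centroid distance (15 | 20 mm). The shipped defaults are
#' `"3_15"`, `"3_20"`, `"5_20"` (CT, steel spheres) and `"6_20"` (MRI).
#'
#' The distance-uniqueness invariants are what the correspondence matcher
#' relies on; they are *validated*, never assumed: all 28 pairwise distances
#' must be mutually separated by more than `tol`, and all 8 per-feature
#' distance signatures must differ in at least one entry by more than `tol`.
#'
#' @param config_id name of a shipped configuration (`"3_15"`, `"3_20"`,
#'   `"5_20"`, `"6_20"`), or an arbitrary id when `centroids` is supplied.
#' @param centroids 8 x 3 numeric matrix of feature centroids, mm, in the
#'   marker coordinate system. If `NULL`, the shipped configuration
#'   `config_id` is loaded.
#' @param feature_diameter sphere diameter, mm.
#' @param modality `"CT"` or `"MRI"`.
#' @param min_feature_distance stated minimum centroid distance, mm (used by
#'   validation; taken from the config file for shipped geometries).
#' @param tol distance-uniqueness tolerance tau, mm. The default 1 mm is
#'   about one in-plane voxel: the matching tolerance must exceed the
#'   centroid estimation error.
#' @param sensorholder_to_marker optional [rigid_transform()] giving the
#'   constant sensor-holder pose relative to the marker (used in transform
#'   chains).
#' @return An object of class `marker_geometry`.
#' @examples
#' geo <- marker_geometry("3_15")
#' expected_feature_volume(geo)
#' @export
marker_geometry <- function(config_id, centroids = NULL, feature_diameter = NULL,
                            modality = c("CT", "MRI"), min_feature_distance = NULL,
                            tol = 1.0, sensorholder_to_marker = NULL) {
  if (is.null(centroids)) {
    path <- system.file("extdata", "markers", paste0(config_id, ".yaml"),
                        package = "fidloc")
    if (!nzchar(path))
      stop("unknown marker configuration '", config_id,
           "'; shipped configurations: ", paste(shipped_marker_configs(), collapse = ", "))
    return(read_marker_geometry(path, tol = tol))
  }
  modality <- match.arg(modality)
  centroids <- unname(as.matrix(centroids))
  if (is.null(feature_diameter) || feature_diameter <= 0)
    stop("feature_diameter must be a positive length in mm")
  geo <- structure(list(
    config_id = as.character(config_id),
    feature_diameter = as.numeric(feature_diameter),
    modality = modality,
    centroids = centroids,
    min_feature_distance = min_feature_distance,
    tol = tol,
    sensorholder_to_marker = sensorholder_to_marker
  ), class = "marker_geometry")
  validate_marker_geometry(geo)
  geo
}

#' @rdname marker_geometry
#' @export
shipped_marker_configs <- function() {
  sub("\\.yaml$", "", list.files(system.file("extdata", "markers", package = "fidloc"),
                                 pattern = "\\.yaml$"))
}

#' Read and write marker geometry configuration files
#'
#' The configuration is a YAML key-value file with fields `id`,
#' `diameter_mm`, `modality`, `centroids_mm` (8 rows of 3) and optional
#' `min_feature_distance_mm` and `sensorholder_to_marker` (4x4 row-major,
#' mm). Validation failures are reported as errors, never silently accepted.
#'
#' @param path file path.
#' @param tol uniqueness tolerance tau in mm passed to validation.
#' @return `read_marker_geometry()` returns a validated [marker_geometry()];
#'   `write_marker_geometry()` returns `path` invisibly.
#' @export
read_marker_geometry <- function(path, tol = 1.0) {
  if (!file.exists(path)) stop("marker geometry config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("id", "diameter_mm", "modality", "centroids_mm"))
    if (is.null(cfg[[f]])) stop("marker geometry config is missing field '", f, "'")
  cen <- cfg$centroids_mm
  if (!is.list(cen) || any(lengths(cen) != 3L))
    stop("'centroids_mm' must be a list of [x, y, z] triples")
  cen <- do.call(rbind, lapply(cen, as.numeric))
  s2m <- NULL
  if (!is.null(cfg$sensorholder_to_marker)) {
    m <- matrix(as.numeric(unlist(cfg$sensorholder_to_marker)), 4L, 4L, byrow = TRUE)
    s2m <- rigid_transform_from_matrix(m)
  }
  marker_geometry(cfg$id, centroids = cen, feature_diameter = cfg$diameter_mm,
                  modality = match.arg(cfg$modality, c("CT", "MRI")),
                  min_feature_distance = cfg$min_feature_distance_mm,
                  tol = tol, sensorholder_to_marker = s2m)
}

#' @rdname read_marker_geometry
#' @param geometry a [marker_geometry()].
#' @export
write_marker_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "marker_geometry"))
  cfg <- list(id = geometry$config_id,
              diameter_mm = geometry$feature_diameter,
              modality = geometry$modality,
              min_feature_distance_mm = geometry$min_feature_distance,
              centroids_mm = lapply(seq_len(nrow(geometry$centroids)),
                                    function(i) as.numeric(geometry$centroids[i, ])))
  if (!is.null(geometry$sensorholder_to_marker))
    cfg$sensorholder_to_marker <- as.numeric(t(as.matrix(geometry$sensorholder_to_marker)))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Validate a marker geometry
#'
#' Checks the structural invariants: exactly 8 centroids; minimum pairwise
#' distance at least the stated minimum; centroids on two parallel planes,
#' four per plane, within `planarity_tol`; all 28 pairwise distances and all
#' 8 distance signatures unique at tolerance `tol`. A geometry with two
#' equal pairwise distances is rejected as ambiguous: the matcher could not
#' distinguish the corresponding feature pairs.
#'
#' @param geometry a [marker_geometry()].
#' @param planarity_tol maximum out-of-plane deviation, mm.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_marker_geometry <- function(geometry, planarity_tol = 0.5) {
  cen <- geometry$centroids
  tol <- geometry$tol
  if (!is.matrix(cen) || nrow(cen) != 8L || ncol(cen) != 3L)
    stop("marker geometry must have exactly 8 centroids (got ",
         if (is.matrix(cen)) nrow(cen) else length(cen), ")")
  if (any(!is.finite(cen))) stop("centroids contain non-finite values")
  d <- sort(as.vector(stats::dist(cen)))
  if (!is.null(geometry$min_feature_distance) &&
      d[1] < geometry$min_feature_distance - 1e-6)
    stop(sprintf("minimum pairwise distance %.3f mm is below the stated minimum %g mm",
                 d[1], geometry$min_feature_distance))
  if (min(diff(d)) <= tol)
    stop(sprintf(paste0("ambiguous geometry: two pairwise distances differ by only ",
                        "%.3f mm (<= tau = %g mm); the distance configuration must be unique"),
                 min(diff(d)), tol))
  # signatures must be pairwise distinct at tau
  sig <- t(vapply(1:8, function(i) distance_signature(geometry, i), numeric(7)))
  for (i in 1:7) for (j in (i + 1):8)
    if (max(abs(sig[i, ] - sig[j, ])) <= tol)
      stop(sprintf("ambiguous geometry: distance signatures of features %d and %d agree within tau", i, j))
  # two parallel planes, four per plane: search all 4/4 splits for a common
  # normal (smallest singular vector of the per-group-centered coordinates)
  best_dev <- Inf
  for (a in utils::combn(8L, 4L, simplify = FALSE)) {
    if (!(1L %in% a)) next  # complementary splits are equivalent
    stacked <- rbind(scale(cen[a, ], scale = FALSE),
                     scale(cen[-a, ], scale = FALSE))
    normal <- svd(stacked)$v[, 3]
    dev <- max(abs(stacked %*% normal))
    if (dev < best_dev) best_dev <- dev
  }
  if (best_dev > planarity_tol)
    stop(sprintf("centroids deviate %.3f mm from two parallel planes (tolerance %g mm)",
                 best_dev, planarity_tol))
  invisible(TRUE)
}

#' Pairwise distance configuration
#'
#' All C(8,2) = 28 centroid-to-centroid distances of the marker, sorted
#' ascending. This multiset is the fingerprint the matcher compares candidate
#' constellations against; it is invariant under any rigid motion of the
#' marker.
#'
#' @param geometry a [marker_geometry()].
#' @return Sorted numeric vector of 28 distances, mm.
#' @export
pairwise_distances <- function(geometry) {
  stopifnot(inherits(geometry, "marker_geometry"))
  sort(as.vector(stats::dist(geometry$centroids)))
}

#' Per-feature distance signature
#'
#' The sorted distances from feature `index` to the seven other features.
#' Because the signatures of a validated geometry are mutually distinct,
#' they identify which canonical feature a detected point corresponds to.
#'
#' @param geometry a [marker_geometry()].
#' @param index feature index, 1..8.
#' @return Sorted numeric vector of 7 distances, mm.
#' @export
distance_signature <- function(geometry, index) {
  stopifnot(inherits(geometry, "marker_geometry"))
  if (length(index) != 1L || is.na(index) || index < 1 || index > 8)
    stop("feature index must be in 1..8")
  cen <- geometry$centroids
  sort(sqrt(colSums((t(cen[-index, , drop = FALSE]) - cen[index, ])^2)))
}

#' Expected physical volume of one fiducial feature
#'
#' Sphere volume (pi/6) d^3 for feature diameter d; the reference value for
#' the candidate volume-pruning rule.
#'
#' @param geometry a [marker_geometry()] (or a numeric diameter in mm).
#' @return Volume in mm^3.
#' @export
expected_feature_volume <- function(geometry) {
  d <- if (inherits(geometry, "marker_geometry")) geometry$feature_diameter else geometry
  stopifnot(is.numeric(d), d > 0)
  pi / 6 * d^3
}

#' @export
print.marker_geometry <- function(x, ...) {
  cat(sprintf("Marker geometry '%s': 8 spherical features, diameter %g mm, %s\n",
              x$config_id, x$feature_diameter, x$modality))
  d <- pairwise_distances(x)
  cat(sprintf("  pairwise distances %.1f-%.1f mm (min gap %.2f mm, tau = %g mm)\n",
              d[1], d[28], min(diff(d)), x$tol))
  invisible(x)
}

#' Modality profile for candidate pruning
#'
#' Encodes the modality-dependent volume-pruning rule: candidates with a
#' physical volume smaller than `lower_volume_factor` (0.6) times the real
#' feature volume are excluded for both CT and MRI; candidates larger than
#' `upper_volume_factor` (2) times the real volume are excluded for MRI
#' only. Fiducial features are bright in both supported modalities.
#'
#' @param modality `"CT"` or `"MRI"`.
#' @param lower_volume_factor dimensionless, in (0, 1).
#' @param upper_volume_factor dimensionless > 1, or `NA` for no upper bound.
#' @return An object of class `modality_profile`.
#' @export
modality_profile <- function(modality = c("CT", "MRI"),
                             lower_volume_factor = 0.6,
                             upper_volume_factor = if (modality == "MRI") 2.0 else NA_real_) {
  modality <- match.arg(modality)
  stopifnot(lower_volume_factor > 0, lower_volume_factor < 1)
  if (!is.na(upper_volume_factor) && upper_volume_factor <= 1)
    stop("upper_volume_factor must exceed 1 when present")
  structure(list(modality = modality,
                 lower_volume_factor = lower_volume_factor,
                 upper_volume_factor = upper_volume_factor,
                 intensity_polarity = "bright"),
            class = "modality_profile")
}
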