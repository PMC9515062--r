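# run code with a local, explicit RNG seed, restoring the caller's state
with_local_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Rendering profile for synthetic volumes
#'
#' Intensity model of the synthetic scans. CT defaults emulate steel
#' spheres in a HU-like scale (background 40, feature 3000, noise sd 15);
#' MRI defaults emulate high-signal spots on tissue (background 100,
#' feature 1000, noise sd 20) with an optional multiplicative bias field —
#' the knob that reproduces the qualitatively worse MRI localization
#' (intensity inhomogeneity shifts intensity-weighted centroids).
#'
#' @param modality `"CT"` or `"MRI"` (selects the intensity defaults).
#' @param feature_intensity,background_intensity scalar intensities.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param blur_fwhm isotropic Gaussian blur FWHM, mm, applied on the
#'   rendered grid (scanner point-spread on top of the exact partial-volume
#'   occupancy).
#' @param bias_amplitude relative amplitude of a smooth multiplicative bias
#'   field (0 disables; only meaningful for MRI).
#' @param supersampling sub-voxel sampling rate per axis for the
#'   partial-volume occupancy (4 bounds the per-voxel occupancy error by
#'   1/64).
#' @param seed integer seed for the stochastic components; no default
#'   wall-clock seeding anywhere.
#' @return An object of class `render_profile`.
#' @export
render_profile <- function(modality = c("CT", "MRI"),
                           feature_intensity = if (modality == "MRI") 1000 else 3000,
                           background_intensity = if (modality == "MRI") 100 else 40,
                           noise_sd = if (modality == "MRI") 20 else 15,
                           blur_fwhm = 0.8, bias_amplitude = 0,
                           supersampling = 4L, seed = 1L) {
  modality <- match.arg(modality)
  stopifnot(feature_intensity > background_intensity, supersampling >= 1L,
            noise_sd >= 0, blur_fwhm >= 0, bias_amplitude >= 0)
  structure(list(modality = modality,
                 feature_intensity = feature_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                 bias_amplitude = bias_amplitude,
                 supersampling = as.integer(supersampling),
                 seed = as.integer(seed)),
            class = "render_profile")
}

#' Render a synthetic marker volume
#'
#' Draws the eight fiducial spheres of a posed marker into a voxel grid.
#' Each voxel value is `background + contrast * occupancy + noise`, where
#' the occupancy is the fraction of the voxel inside a sphere, computed by
#' supersampled sub-voxel sampling (exact to `1 / supersampling^3`), then
#' optionally blurred by the profile's point-spread. Emulates one scan of
#' one marker pose; the ground-truth pose is returned alongside.
#'
#' @param geometry a [marker_geometry()].
#' @param pose a [rigid_transform()], marker to image world.
#' @param profile a [render_profile()].
#' @param spacing length-3 voxel spacing, mm.
#' @param margin empty border around the transformed marker, mm; the volume
#'   extent defaults to the marker bounding box plus this margin.
#' @param extent optional physical extent (length-3, mm) centered on the
#'   transformed marker centroid, overriding the automatic extent.
#' @param direction 3x3 orthonormal voxel-axis directions of the grid.
#' @return A list with `volume` (a [med_volume()]), `pose` (the ground
#'   truth) and `feature_centers` (8 x 3 world coordinates).
#' @export
render_marker_volume <- function(geometry, pose, profile = render_profile(geometry$modality),
                                 spacing = c(0.98, 0.98, 1),
                                 margin = 12, extent = NULL, direction = diag(3)) {
  stopifnot(inherits(geometry, "marker_geometry"), inherits(pose, "rigid_transform"),
            inherits(profile, "render_profile"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be three positive lengths in mm")
  centers <- transform_points(pose, geometry$centroids)
  rad <- geometry$feature_diameter / 2
  # grid axes follow `direction`; work in grid-aligned coordinates
  cg <- centers %*% direction
  ctr <- (apply(cg, 2, min) + apply(cg, 2, max)) / 2
  half <- if (is.null(extent)) (apply(cg, 2, max) - apply(cg, 2, min)) / 2 + margin
          else as.numeric(extent) / 2
  dims <- pmax(as.integer(ceiling(2 * half / spacing)), 3L)
  origin_g <- ctr - (dims - 1) / 2 * spacing
  pad <- rad + profile$blur_fwhm + 0.5 * voxel_diagonal(spacing)
  if (any(cg < matrix(origin_g, nrow(cg), 3, byrow = TRUE) - spacing / 2 + pad) ||
      any(cg > matrix(origin_g + (dims - 1) * spacing, nrow(cg), 3, byrow = TRUE) + spacing / 2 - pad))
    stop("feature truncated: a fiducial feature (plus blur) extends outside the volume extent")
  arr <- array(0, dims)
  ss <- profile$supersampling
  offs <- ((seq_len(ss) - 0.5) / ss - 0.5)
  og <- as.matrix(expand.grid(ox = offs * spacing[1], oy = offs * spacing[2],
                              oz = offs * spacing[3]))
  for (f in seq_len(nrow(cg))) {
    arr <- add_sphere_occupancy(arr, cg[f, ], rad, spacing, origin_g, og)
  }
  vox <- profile$background_intensity +
    (profile$feature_intensity - profile$background_intensity) * arr
  if (profile$blur_fwhm > 0)
    vox <- gaussian_smooth(vox, profile$blur_fwhm / (2 * sqrt(2 * log(2))), spacing)
  vox <- with_local_seed(profile$seed, {
    out <- vox
    if (profile$bias_amplitude > 0) {
      dir3 <- stats::rnorm(3); dir3 <- dir3 / sqrt(sum(dir3^2))
      ix <- (seq_len(dims[1]) - 1) / max(dims[1] - 1, 1) - 0.5
      iy <- (seq_len(dims[2]) - 1) / max(dims[2] - 1, 1) - 0.5
      iz <- (seq_len(dims[3]) - 1) / max(dims[3] - 1, 1) - 0.5
      bias <- 1 + profile$bias_amplitude *
        (outer(outer(ix * dir3[1], iy * dir3[2], "+"), iz * dir3[3], "+"))
      out <- out * bias
    }
    if (profile$noise_sd > 0)
      out <- out + stats::rnorm(length(out), 0, profile$noise_sd)
    out
  })
  world_origin <- drop(direction %*% origin_g)
  vol <- med_volume(vox, spacing = spacing, origin = world_origin,
                    direction = direction, modality = profile$modality)
  list(volume = vol, pose = pose, feature_centers = centers)
}

# accumulate the partial-volume occupancy of one sphere into arr
add_sphere_occupancy <- function(arr, center_g, radius, spacing, origin_g, subgrid) {
  dims <- dim(arr)
  lo <- pmax(floor((center_g - radius - origin_g) / spacing) + 1L - 1L, 1L)
  hi <- pmin(ceiling((center_g + radius - origin_g) / spacing) + 1L + 1L, dims)
  xs <- origin_g[1] + (seq(lo[1], hi[1]) - 1) * spacing[1]
  ys <- origin_g[2] + (seq(lo[2], hi[2]) - 1) * spacing[2]
  zs <- origin_g[3] + (seq(lo[3], hi[3]) - 1) * spacing[3]
  gg <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  frac <- numeric(nrow(gg))
  r2 <- radius^2
  # quick classification by voxel-center distance, supersample the shell band
  d2 <- (gg[, 1] - center_g[1])^2 + (gg[, 2] - center_g[2])^2 + (gg[, 3] - center_g[3])^2
  halfdiag <- 0.5 * sqrt(sum(spacing^2))
  inside <- sqrt(d2) <= radius - halfdiag
  outside <- sqrt(d2) >= radius + halfdiag
  frac[inside] <- 1
  band <- which(!inside & !outside)
  for (i in band) {
    pts <- sweep(subgrid, 2L, as.numeric(gg[i, ]), "+")
    frac[i] <- mean((pts[, 1] - center_g[1])^2 + (pts[, 2] - center_g[2])^2 +
                      (pts[, 3] - center_g[3])^2 <= r2)
  }
  blk <- array(frac, dim = c(length(xs), length(ys), length(zs)))
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blk
  arr
}

#' Six-station phantom specification
#'
#' Geometry of the point-symmetric assessment phantoms. Six docking
#' stations lie on a circle of `station_radius` (100 mm) around the
#' symmetry point in the z = 0 plane, at 60 degree steps, so stations i and
#' i+3 are antipodal. Station pose i is `Rz(60 i) o T0`; the *angle*
#' variant additionally tilts `T0` toward the symmetry axis by `tilt`
#' degrees. Virtual targets sit on the symmetry axis at the given depths
#' below the station plane and are expressed in the marker frame, so that
#' by construction every ideal station pose maps each target to the same
#' world point (ideal PPE = 0); the 100 mm target carries the index
#' `"P100"`.
#'
#' @param kind `"plane"` (tilt 0) or `"angle"`.
#' @param station_radius symmetry-point-to-station distance, mm.
#' @param n_stations number of stations; the PPE definition expects 6.
#' @param tilt station tilt toward the symmetry axis, degrees (angle
#'   phantom).
#' @param symmetry_point world position of the symmetry point, mm.
#' @param target_depths depths of the virtual targets along the symmetry
#'   axis, mm.
#' @param orientation optional [rigid_transform()] applied globally to the
#'   whole phantom (stations and targets move together; PPE is invariant).
#' @return An object of class `phantom_spec` with the ground-truth station
#'   `transforms` and `virtual_targets` (marker frame, rows named
#'   `P<depth>`).
#' @export
phantom_spec <- function(kind = c("plane", "angle"), station_radius = 100,
                         n_stations = 6L, tilt = if (kind == "angle") 30 else 0,
                         symmetry_point = c(0, 0, 0),
                         target_depths = c(25, 50, 75, 100, 150, 175),
                         orientation = NULL) {
  kind <- match.arg(kind)
  stopifnot(station_radius > 0, n_stations >= 2L, n_stations %% 2L == 0L)
  if (kind == "plane" && tilt != 0) stop("the plane phantom has tilt 0")
  t0 <- rigid_transform(rotation_about_axis("y", -tilt),
                        symmetry_point + c(station_radius, 0, 0))
  transforms <- lapply(seq_len(n_stations) - 1L, function(i) {
    rz <- rigid_transform(rotation_about_axis("z", 360 / n_stations * i), c(0, 0, 0))
    about <- rigid_transform(diag(3), symmetry_point)
    compose(compose(about, rz), compose(invert(about), t0))
  })
  axis_points <- cbind(symmetry_point[1], symmetry_point[2],
                       symmetry_point[3] - target_depths)
  it0 <- invert(t0)
  targets <- transform_points(it0, axis_points)
  rownames(targets) <- paste0("P", target_depths)
  if (!is.null(orientation)) {
    stopifnot(is_rigid_transform(orientation))
    transforms <- lapply(transforms, function(tf) compose(orientation, tf))
    symmetry_point <- transform_points(orientation, symmetry_point)
  }
  spec <- structure(list(kind = kind, station_radius = station_radius,
                         n_stations = as.integer(n_stations), tilt = tilt,
                         symmetry_point = symmetry_point,
                         target_depths = target_depths,
                         virtual_targets = targets,
                         transforms = transforms),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stations <- t(vapply(spec$transforms, function(tf) tf$translation, numeric(3)))
  r <- sqrt(rowSums(sweep(stations, 2L, spec$symmetry_point)^2))
  if (max(abs(r - spec$station_radius)) > 1e-6)
    stop("phantom spec violates the station radius")
  n <- spec$n_stations
  anti <- stations[1:(n / 2), , drop = FALSE] + stations[(n / 2 + 1):n, , drop = FALSE]
  if (max(abs(sweep(anti / 2, 2L, spec$symmetry_point))) > 1e-6)
    stop("phantom spec violates point symmetry: stations i and i + n/2 must be antipodal")
  invisible(TRUE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("%s phantom: %d stations at %g mm around (%g, %g, %g), tilt %g deg\n",
              x$kind, x$n_stations, x$station_radius, x$symmetry_point[1],
              x$symmetry_point[2], x$symmetry_point[3], x$tilt))
  cat("  virtual targets:", paste(rownames(x$virtual_targets), collapse = ", "), "\n")
  invisible(x)
}

#' Render a full phantom series
#'
#' One synthetic scan per docking station, emulating the assessment
#' procedure in which the marker is mounted consecutively to each station
#' and one volume is acquired per pose. Per-station noise is seeded
#' reproducibly from the profile seed.
#'
#' @param spec a [phantom_spec()].
#' @param geometry a [marker_geometry()].
#' @param profile a [render_profile()].
#' @param spacing voxel spacing, mm.
#' @param ... passed to [render_marker_volume()].
#' @return A list with `volumes` (list of [med_volume()]), `transforms`
#'   (ground truth), `virtual_targets` and `spec`.
#' @export
make_phantom_series <- function(spec, geometry, profile = render_profile(geometry$modality),
                                spacing = c(0.98, 0.98, 1), ...) {
  stopifnot(inherits(spec, "phantom_spec"))
  rendered <- lapply(seq_along(spec$transforms), function(i) {
    pr <- profile
    pr$seed <- profile$seed + i - 1L
    render_marker_volume(geometry, spec$transforms[[i]], pr, spacing = spacing, ...)
  })
  list(volumes = lapply(rendered, `[[`, "volume"),
       transforms = spec$transforms,
       virtual_targets = spec$virtual_targets,
       spec = spec)
}

#' Inject bright distractor blobs
#'
#' Adds `n` ellipsoidal bright blobs at seeded random positions to stress
#' the volume-pruning and distance-matching rules. Blobs keep a minimum
#' separation from the positions in `avoid` (e.g. the true feature
#' centers) and from each other.
#'
#' @param volume a [med_volume()].
#' @param n number of distractors.
#' @param diameter_range min/max blob diameter, mm.
#' @param intensity_range min/max blob peak intensity (added on top of the
#'   existing voxel values).
#' @param seed integer seed.
#' @param avoid optional m x 3 matrix of world points to stay away from.
#' @param min_separation minimum center distance to `avoid` points and
#'   between blobs, mm.
#' @param margin keep blob centers this far from the volume faces, mm.
#' @return The volume with distractors added; attribute
#'   `distractor_centers` holds the placed world positions.
#' @export
inject_distractors <- function(volume, n, diameter_range = c(2.5, 4.5),
                               intensity_range = c(1500, 3000), seed = 1L,
                               avoid = NULL, min_separation = NULL, margin = 4) {
  stopifnot(inherits(volume, "med_volume"), n >= 0)
  if (n == 0L) return(volume)
  if (is.null(min_separation)) min_separation <- 2 * max(diameter_range)
  d <- dim(volume$voxels)
  lo_g <- margin + diameter_range[2] / 2
  ext <- (d - 1) * volume$spacing
  if (any(ext <= 2 * lo_g)) stop("volume too small to place distractors")
  origin_g <- drop(t(volume$direction) %*% volume$origin)  # grid-aligned origin
  placed <- matrix(numeric(0), 0, 3)
  out <- volume
  with_local_seed(seed, {
    ss <- 2L
    offs <- ((seq_len(ss) - 0.5) / ss - 0.5)
    og <- as.matrix(expand.grid(ox = offs * volume$spacing[1],
                                oy = offs * volume$spacing[2],
                                oz = offs * volume$spacing[3]))
    for (k in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cg <- origin_g + lo_g + stats::runif(3) * (ext - 2 * lo_g)
        world <- drop(volume$direction %*% cg)
        pts <- rbind(if (!is.null(avoid)) as.matrix(avoid), placed)
        if (nrow(pts) > 0 &&
            min(sqrt(rowSums(sweep(pts, 2L, world)^2))) < min_separation) next
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place distractor ", k, " after 1000 tries; ",
                    "reduce n or min_separation")
      diam <- stats::runif(1, diameter_range[1], diameter_range[2])
      axes <- diam / 2 * stats::runif(3, 0.75, 1.25)
      amp <- stats::runif(1, intensity_range[1], intensity_range[2])
      occ <- array(0, d)
      # render the ellipsoid as a sphere in per-axis-scaled coordinates
      sc <- max(axes) / axes
      occ <- add_sphere_occupancy(occ, cg * sc, max(axes), volume$spacing * sc,
                                  origin_g * sc, og)
      out$voxels <- out$voxels + amp * occ
      placed <- rbind(placed, world)
    }
    invisible(NULL)
  })
  attr(out, "distractor_centers") <- placed
  out
}

#' Reslice a volume to a thicker slice spacing
#'
#' Emulates thick-slice reconstructions by slab-averaging along the slice
#' axis with thickness = spacing = `new_thickness`. For non-integer
#' thickness ratios the slab boundaries fall on the nearest original
#' slice (nearest-neighbour slab assignment); total intensity times volume
#' is conserved up to the partial trailing slab.
#'
#' @param volume a [med_volume()].
#' @param new_thickness target slice thickness, mm; must not be below the
#'   current slice spacing.
#' @return The resliced [med_volume()].
#' @export
reslice <- function(volume, new_thickness) {
  stopifnot(inherits(volume, "med_volume"))
  dz <- volume$spacing[3]
  if (new_thickness < dz - 1e-9)
    stop("new_thickness must be at least the current slice spacing (", dz, " mm)")
  ratio <- new_thickness / dz
  if (abs(ratio - 1) < 1e-9) return(volume)
  d <- dim(volume$voxels)
  slab <- floor(((seq_len(d[3]) - 0.5) * dz) / new_thickness)
  nz <- max(slab) + 1L
  arr <- array(0, c(d[1], d[2], nz))
  for (s in seq_len(nz) - 1L) {
    idx <- which(slab == s)
    arr[, , s + 1L] <- if (length(idx) == 1L) volume$voxels[, , idx]
      else apply(volume$voxels[, , idx, drop = FALSE], c(1, 2), mean)
  }
  # slab centers: first slab spans [0, new), centered at new/2; original
  # slice 0 sits at its cell center dz/2, so shift the origin accordingly
  shift <- (new_thickness - dz) / 2
  med_volume(arr, spacing = c(volume$spacing[1:2], new_thickness),
             origin = volume$origin + volume$direction[, 3] * shift,
             direction = volume$direction, modality = volume$modality)
}
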