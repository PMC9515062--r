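#' Background suppression
#'
#' First stage of the candidate-detection pipeline: negligible soft-tissue
#' signal is removed by setting every voxel below an automatically chosen
#' intensity threshold to the volume minimum. The threshold is self
#' adjusting: the `percentile` intensity cutoff, raised to a modality floor
#' (300 HU for CT when the intensity range is HU-like, i.e. contains values
#' below -200; MRI has no absolute scale, hence no floor). The chosen
#' threshold is reported in the `threshold` attribute of the result.
#'
#' @param volume a [med_volume()].
#' @param profile a [modality_profile()].
#' @param percentile intensity percentile in (0, 1) defining the adaptive
#'   cutoff; default 0.995 keeps the brightest 0.5 % of voxels, robust to
#'   field-of-view changes since the marker occupies far less than that.
#' @return The suppressed [med_volume()], with attributes `threshold` and
#'   `n_survivors`.
#' @export
suppress_background <- function(volume, profile = modality_profile("CT"),
                                percentile = 0.995) {
  stopifnot(inherits(volume, "med_volume"), percentile > 0, percentile < 1)
  v <- volume$voxels
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("no foreground: volume has constant intensity")
  thr <- as.numeric(stats::quantile(v, percentile, names = FALSE))
  if (profile$modality == "CT" && rng[1] <= -200) thr <- max(thr, 300)
  out <- volume
  keep <- v >= thr & v > rng[1]
  out$voxels[!keep] <- min(v)
  n_surv <- sum(keep)
  if (n_surv == 0L) stop("no foreground: no voxel exceeds the suppression threshold")
  attr(out, "threshold") <- thr
  attr(out, "n_survivors") <- n_surv
  out
}

#' Edge response
#'
#' Gradient magnitude of the Gaussian-smoothed volume, the second pipeline
#' stage. Fiducial features are characterized by the large voxel-value
#' gradients of their edge regions; the derivative scale sigma =
#' `feature_diameter / 6` mm places the peak response on a shell at roughly
#' half the feature diameter while averaging over noise. Smoothing and
#' differentiation respect anisotropic spacing (sigma is converted to
#' voxels per axis; derivatives are per mm).
#'
#' @param volume a [med_volume()].
#' @param feature_diameter fiducial feature diameter, mm.
#' @return A [med_volume()] of gradient magnitudes (intensity units per mm).
#' @export
edge_response <- function(volume, feature_diameter) {
  stopifnot(inherits(volume, "med_volume"), feature_diameter > 0)
  sm <- gaussian_smooth(volume$voxels, feature_diameter / 6, volume$spacing)
  g2 <- array(0, dim(sm))
  for (ax in 1:3) g2 <- g2 + central_diff(sm, ax, volume$spacing[ax])^2
  out <- volume
  out$voxels <- sqrt(g2)
  out
}

# separable Gaussian smoothing, sigma in mm, per-axis voxel conversion
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  for (ax in 1:3) {
    sv <- sigma_mm / spacing[ax]
    r <- as.integer(ceiling(3 * sv))
    if (r < 1L) next
    k <- exp(-0.5 * ((-r:r) / sv)^2)
    arr <- convolve_axis(arr, k / sum(k), ax)
  }
  arr
}

# convolution along one axis with edge replication, via BLAS matmul
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  n <- d[axis]
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  # K[i, j] = kernel weight of padded row j contributing to output row i
  ker <- matrix(0, n, n + 2L * r)
  for (o in seq_along(kernel)) ker[cbind(1:n, 1:n + o - 1L)] <- kernel[o]
  out <- ker %*% mp
  aperm(array(out, d[perm]), order(perm))
}

central_diff <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 3L) return(array(0, d))
  idx_hi <- c(2:n, n); idx_lo <- c(1L, 1:(n - 1L))
  sl <- function(i) switch(axis, arr[i, , , drop = FALSE],
                           arr[, i, , drop = FALSE], arr[, , i, drop = FALSE])
  step <- pmin(idx_hi - idx_lo, 2L) * h  # one-sided at the faces
  g <- (sl(idx_hi) - sl(idx_lo))
  sweep_axis(g, step, axis)
}

sweep_axis <- function(arr, vals, axis) {
  d <- dim(arr)
  rep_each <- prod(d[seq_len(axis - 1L)])
  rep_times <- prod(d[seq_len(3L - axis) + axis])
  arr / array(rep(rep(vals, each = rep_each), times = rep_times), d)
}

# Otsu's two-class threshold on a numeric vector
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(as.integer((x - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L, nbins),
                nbins)
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nbins))
  tot_w <- w[nbins]; tot_mu <- mu[nbins]
  w1 <- w[-nbins]; mu1 <- mu[-nbins]
  w2 <- tot_w - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu1[valid] / w1[valid] - (tot_mu - mu1[valid]) / w2[valid])^2 *
    w1[valid] * w2[valid]
  k <- which.max(bcv)
  rng[1] + k / nbins * (rng[2] - rng[1])
}

# 26- or 6-connected components of a logical 3-D mask; returns an integer
# vector of component labels aligned with which(mask)
label_mask_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  nfg <- length(idx)
  if (nfg == 0L) return(list(idx = idx, labels = integer(0), n = 0L))
  map <- integer(prod(d))
  map[idx] <- seq_len(nfg)
  co <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # half the neighbourhood suffices for an undirected adjacency
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ok <- co[, 1] + o[1] >= 1L & co[, 1] + o[1] <= d[1] &
          co[, 2] + o[2] >= 1L & co[, 2] + o[2] <= d[2] &
          co[, 3] + o[3] >= 1L & co[, 3] + o[3] <= d[3]
    nb <- idx[ok] + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    j <- map[nb]
    hit <- j > 0L
    from <- c(from, map[idx[ok]][hit])
    to <- c(to, j[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = nfg, directed = FALSE)
  comp <- igraph::components(g)
  list(idx = idx, labels = comp$membership, n = comp$no)
}

# fill interior cavities of a mask, per component, within its bounding box
fill_holes <- function(mask, lab = label_mask_components(mask)) {
  d <- dim(mask)
  if (lab$n == 0L) return(mask)
  co <- arrayInd(lab$idx, d)
  out <- mask
  for (cid in seq_len(lab$n)) {
    sel <- lab$labels == cid
    lo <- pmax(apply(co[sel, , drop = FALSE], 2, min) - 1L, 1L)
    hi <- pmin(apply(co[sel, , drop = FALSE], 2, max) + 1L, d)
    sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    ds <- dim(sub)
    # flood the complement from the box faces (6-connected dilation to fixpoint)
    open_ <- !sub
    reach <- array(FALSE, ds)
    reach[1, , ] <- open_[1, , ]; reach[ds[1], , ] <- open_[ds[1], , ]
    reach[, 1, ] <- reach[, 1, ] | open_[, 1, ]; reach[, ds[2], ] <- reach[, ds[2], ] | open_[, ds[2], ]
    reach[, , 1] <- reach[, , 1] | open_[, , 1]; reach[, , ds[3]] <- reach[, , ds[3]] | open_[, , ds[3]]
    repeat {
      grown <- reach
      grown[-1, , ] <- grown[-1, , ] | reach[-ds[1], , ]
      grown[-ds[1], , ] <- grown[-ds[1], , ] | reach[-1, , ]
      grown[, -1, ] <- grown[, -1, ] | reach[, -ds[2], ]
      grown[, -ds[2], ] <- grown[, -ds[2], ] | reach[, -1, ]
      grown[, , -1] <- grown[, , -1] | reach[, , -ds[3]]
      grown[, , -ds[3]] <- grown[, , -ds[3]] | reach[, , -1]
      grown <- grown & open_
      if (identical(grown, reach)) break
      reach <- grown
    }
    filled <- sub | (!reach & open_)
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | filled
  }
  out
}

#' Binarize and label candidate features
#'
#' Third pipeline stage: combines the suppressed intensities with the edge
#' response into a binary foreground, labels its 26-connected components
#' and summarizes each component as a candidate feature. The foreground is
#' the set of suppression survivors lying inside the (hole-filled) strong
#' edge shell, where "strong" is an automatic two-class (Otsu) threshold on
#' the nonzero edge responses: intensity alone would admit isolated bright
#' noise voxels, edges alone would give hollow shells, the intersection
#' gives solid, compact candidates. Components touching the volume boundary
#' are discarded (a feature must be completely captured to be usable), and
#' centroids are intensity-weighted world coordinates for sub-voxel
#' accuracy at thick slices.
#'
#' @param suppressed output of [suppress_background()].
#' @param edges output of [edge_response()] on the same grid.
#' @param max_candidates error out above this component count (a volume this
#'   noisy needs a different threshold percentile).
#' @return A data frame of candidate features (class `candidate_features`):
#'   `label_id`, `x`, `y`, `z` (world centroid, mm), `voxel_count`,
#'   `physical_volume` (mm^3), `mean_intensity`; attributes
#'   `edge_threshold`, `n_components`, `n_border_dropped` and `labels` (the
#'   integer label array).
#' @export
binarize_and_label <- function(suppressed, edges, max_candidates = 500L) {
  stopifnot(inherits(suppressed, "med_volume"), inherits(edges, "med_volume"))
  if (!identical(dim(suppressed$voxels), dim(edges$voxels)))
    stop("suppressed and edge volumes must share one grid")
  v <- suppressed$voxels
  vmin <- min(v)
  survivors <- v > vmin
  e <- edges$voxels
  enz <- e[e > 0]
  if (length(enz) == 0L || !any(survivors)) {
    return(empty_candidates(suppressed, NA_real_))
  }
  ethr <- otsu_threshold(enz)
  shell <- e > ethr
  shell_filled <- fill_holes(shell)
  fg <- survivors & shell_filled
  lab <- label_mask_components(fg)
  if (lab$n > max_candidates)
    stop("noisy volume: ", lab$n, " candidate components exceed max_candidates = ",
         max_candidates, "; raise the suppression percentile")
  if (lab$n == 0L) return(empty_candidates(suppressed, ethr))
  # partial-volume-corrected component size: the raw thresholded component
  # carries a halo of partial voxels that inflates its voxel count, while
  # the occupancy integral sum(v - bg) / peak estimates the true number of
  # occupied voxels independently of slice thickness (the intensity
  # integral of a blurred sphere is conserved). The corrected count feeds
  # the volume rule; the centroid keeps the full halo support, whose
  # intensity weighting carries the sub-voxel position information.
  w_all <- v[lab$idx] - vmin
  corrected_count <- vapply(seq_len(lab$n), function(cid) {
    w <- w_all[lab$labels == cid]
    min(length(w), max(1L, as.integer(round(sum(w) / max(w)))))
  }, integer(1))
  d <- dim(v)
  co <- arrayInd(lab$idx, d)
  border <- co[, 1] == 1L | co[, 1] == d[1] | co[, 2] == 1L | co[, 2] == d[2] |
            co[, 3] == 1L | co[, 3] == d[3]
  border_comp <- unique(lab$labels[border])
  w <- v[lab$idx] - vmin
  f <- factor(lab$labels, levels = seq_len(lab$n))
  wsum <- as.numeric(tapply(w, f, sum))
  # intensity-weighted centroid in continuous 0-based voxel coordinates
  cx <- as.numeric(tapply(w * (co[, 1] - 1), f, sum)) / wsum
  cy <- as.numeric(tapply(w * (co[, 2] - 1), f, sum)) / wsum
  cz <- as.numeric(tapply(w * (co[, 3] - 1), f, sum)) / wsum
  cnt <- corrected_count
  world <- voxel_to_world(suppressed, cbind(cx, cy, cz))
  cand <- data.frame(label_id = seq_len(lab$n),
                     x = world[, 1], y = world[, 2], z = world[, 3],
                     voxel_x = cx, voxel_y = cy, voxel_z = cz,
                     voxel_count = cnt,
                     physical_volume = cnt * voxel_volume(suppressed),
                     mean_intensity = as.numeric(tapply(v[lab$idx], f, mean)))
  keep <- !(cand$label_id %in% border_comp)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  labels_arr <- array(0L, d)
  labels_arr[lab$idx] <- lab$labels
  structure(out, class = c("candidate_features", "data.frame"),
            edge_threshold = ethr, n_components = lab$n,
            n_border_dropped = sum(!keep), labels = labels_arr)
}

empty_candidates <- function(volume, ethr) {
  structure(data.frame(label_id = integer(0), x = numeric(0), y = numeric(0),
                       z = numeric(0), voxel_x = numeric(0), voxel_y = numeric(0),
                       voxel_z = numeric(0), voxel_count = integer(0),
                       physical_volume = numeric(0), mean_intensity = numeric(0)),
            class = c("candidate_features", "data.frame"),
            edge_threshold = ethr, n_components = 0L, n_border_dropped = 0L,
            labels = array(0L, dim(volume$voxels)))
}

#' Prune candidates by physical volume
#'
#' Excludes candidates whose physical volume is smaller than
#' `lower_volume_factor` (0.6) times the real fiducial feature volume, and
#' for MRI also those greater than `upper_volume_factor` (2) times it (CT
#' has no upper bound: metal features may bloom bright). Fewer than eight
#' survivors is not an error here; localization reports the failure status.
#'
#' @param candidates a `candidate_features` data frame.
#' @param geometry a [marker_geometry()].
#' @param profile a [modality_profile()].
#' @return The pruned candidate data frame, with attributes `volume_bounds`
#'   and `n_pruned`.
#' @export
prune_candidates_by_volume <- function(candidates, geometry,
                                       profile = modality_profile(geometry$modality)) {
  vf <- expected_feature_volume(geometry)
  lo <- profile$lower_volume_factor * vf
  hi <- if (is.na(profile$upper_volume_factor)) Inf else profile$upper_volume_factor * vf
  keep <- candidates$physical_volume >= lo & candidates$physical_volume <= hi
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "volume_bounds") <- c(lower = lo, upper = hi)
  attr(out, "n_pruned") <- sum(!keep)
  class(out) <- c("candidate_features", "data.frame")
  out
}

#' Detect fiducial feature candidates
#'
#' Runs the full self-adjusting pipeline — background suppression, edge
#' response, binarization/labeling, volume pruning — and returns the pruned
#' candidate list together with the per-stage counts and chosen thresholds
#' (attribute `counts`), mirroring the pipeline stages for debuggability.
#' Deterministic for fixed input and configuration. A volume with no usable
#' foreground (e.g. air only) yields an empty candidate list, not an error.
#'
#' @inheritParams suppress_background
#' @inheritParams binarize_and_label
#' @param geometry a [marker_geometry()].
#' @param verbose print per-stage counts.
#' @return A `candidate_features` data frame with attribute `counts`.
#' @export
detect_candidates <- function(volume, geometry,
                              profile = modality_profile(geometry$modality),
                              percentile = 0.995, max_candidates = 500L,
                              verbose = FALSE) {
  edg <- NULL
  used_percentile <- percentile
  cand <- NULL
  # self-adjustment: if the component count overflows, tighten the
  # suppression percentile (quartering the admitted tail) and retry
  for (attempt in 1:4) {
    sup <- tryCatch(suppress_background(volume, profile, used_percentile),
                    error = function(e) {
                      if (grepl("no foreground", conditionMessage(e))) NULL else stop(e)
                    })
    if (is.null(sup)) {
      out <- empty_candidates(volume, NA_real_)
      attr(out, "counts") <- list(threshold = NA_real_, n_survivors = 0L,
                                  edge_threshold = NA_real_, n_components = 0L,
                                  n_border_dropped = 0L, n_pruned = 0L, n_final = 0L,
                                  percentile_used = used_percentile)
      return(out)
    }
    if (is.null(edg)) edg <- edge_response(volume, geometry$feature_diameter)
    cand <- tryCatch(binarize_and_label(sup, edg, max_candidates = max_candidates),
                     error = function(e) {
                       if (attempt < 4L && grepl("noisy volume", conditionMessage(e))) NULL
                       else stop(e)
                     })
    if (!is.null(cand)) break
    used_percentile <- 1 - (1 - used_percentile) / 4
    if (verbose) message(sprintf("detect: noisy volume, raising percentile to %.5f",
                                 used_percentile))
  }
  pruned <- prune_candidates_by_volume(cand, geometry, profile)
  counts <- list(percentile_used = used_percentile,
                 threshold = attr(sup, "threshold"),
                 n_survivors = attr(sup, "n_survivors"),
                 edge_threshold = attr(cand, "edge_threshold"),
                 n_components = attr(cand, "n_components"),
                 n_border_dropped = attr(cand, "n_border_dropped"),
                 n_pruned = attr(pruned, "n_pruned"),
                 n_final = nrow(pruned))
  if (verbose)
    message(sprintf("detect: threshold %.4g, %d survivors -> %d components (%d border, %d volume-pruned) -> %d candidates",
                    counts$threshold, counts$n_survivors, counts$n_components,
                    counts$n_border_dropped, counts$n_pruned, counts$n_final))
  attr(pruned, "counts") <- counts
  pruned
}
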