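# candidate-to-geometry correspondence by pairwise-distance configuration

# minimal-cost bijection of an 8x8 (or smaller square) cost matrix by
# depth-first branch and bound with a per-row-minimum lower bound
solve_assignment <- function(cost) {
  n <- nrow(cost)
  best_perm <- integer(n); best_cost <- Inf
  row_min_tail <- rev(cumsum(rev(apply(cost, 1L, min))))
  recurse <- function(row, used, acc, perm) {
    if (row > n) {
      if (acc < best_cost) { best_cost <<- acc; best_perm <<- perm }
      return(invisible())
    }
    bound_rest <- if (row < n) row_min_tail[row + 1L] else 0
    ord <- order(cost[row, ])
    for (j in ord) {
      if (used[j]) next
      a <- acc + cost[row, j]
      if (a + bound_rest >= best_cost) next
      used[j] <- TRUE; perm[row] <- j
      recurse(row + 1L, used, a, perm)
      used[j] <- FALSE
    }
  }
  recurse(1L, logical(n), 0, integer(n))
  list(assignment = best_perm, cost = best_cost)
}

# sorted distance signature of point i within point set p (n x 3)
point_signature <- function(p, i) {
  sort(sqrt(colSums((t(p[-i, , drop = FALSE]) - p[i, ])^2)))
}

#' Match candidate features to the marker geometry
#'
#' Establishes the ordered candidate-to-feature correspondence from the
#' marker's unique pairwise-distance configuration, in three stages:
#'
#' 1. *Iterative exclusion* — each candidate is scored by how many of its
#'    distances to the other candidates match (within `tau`) any canonical
#'    pairwise distance; while more than eight candidates remain, the
#'    lowest-scoring one is dropped and the rest rescored. Ties break
#'    deterministically: largest deviation of the physical volume from the
#'    expected feature volume, then lowest mean intensity, then lowest
#'    label id.
#' 2. *Ordering* — the eight survivors are assigned to geometry indices by
#'    the one-to-one assignment minimizing the total L1 discrepancy between
#'    candidate and canonical distance signatures.
#' 3. *Verification* — a Horn fit of the assignment; the fit is accepted if
#'    its FRE is at most `fre_threshold`. Otherwise all 8-subsets of the
#'    best (at most `max_exhaustive`) candidates are searched exhaustively,
#'    and the subset/ordering with minimal FRE under the threshold wins.
#'
#' @param candidates a `candidate_features` data frame (>= 8 rows) from
#'   [detect_candidates()], or any data frame with columns `x`, `y`, `z`
#'   (optionally `physical_volume`, `mean_intensity`, `label_id` for tie
#'   breaking).
#' @param geometry a [marker_geometry()].
#' @param tau distance-match tolerance, mm.
#' @param fre_threshold acceptance residual for the Horn fit, mm.
#' @param max_exhaustive cap on the candidate pool for the exhaustive
#'   fallback (16 candidates = 12870 subsets); beyond the cap the extra
#'   lowest-scoring candidates are not considered.
#' @return A list with `status` (`"success"`, `"insufficient_candidates"`,
#'   `"no_consistent_subset"` or `"high_residual"`), and on success
#'   `selected` (row indices into `candidates`, ordered by geometry feature
#'   index 1..8), `transform`, `fre`, `residuals` and `stage` (`"direct"`
#'   or `"exhaustive"`).
#' @export
match_candidates_to_geometry <- function(candidates, geometry, tau = 1.0,
                                         fre_threshold = 1.0,
                                         max_exhaustive = 16L) {
  n_all <- nrow(candidates)
  if (n_all < 8L) return(list(status = "insufficient_candidates", n_candidates = n_all))
  pts <- as.matrix(candidates[, c("x", "y", "z")])
  vol_dev <- if ("physical_volume" %in% names(candidates))
    abs(candidates$physical_volume - expected_feature_volume(geometry)) else rep(0, n_all)
  intensity <- if ("mean_intensity" %in% names(candidates))
    candidates$mean_intensity else rep(0, n_all)
  label <- if ("label_id" %in% names(candidates)) candidates$label_id else seq_len(n_all)
  canon <- pairwise_distances(geometry)
  dist_matches_canon <- function(dv) {
    vapply(dv, function(x) any(abs(x - canon) <= tau), logical(1))
  }
  # stage 1: iterative exclusion
  active <- seq_len(n_all)
  dm <- as.matrix(stats::dist(pts))
  while (length(active) > 8L) {
    sub <- dm[active, active, drop = FALSE]
    score <- vapply(seq_along(active), function(i)
      sum(dist_matches_canon(sub[i, -i])), integer(1))
    ord <- order(score, -vol_dev[active], intensity[active], label[active])
    active <- active[-ord[1L]]
  }
  geo_sig <- t(vapply(1:8, function(i) distance_signature(geometry, i), numeric(7)))
  fit_subset <- function(sel) {
    p <- pts[sel, , drop = FALSE]
    cand_sig <- t(vapply(1:8, function(i) point_signature(p, i), numeric(7)))
    cost <- matrix(0, 8, 8)
    for (i in 1:8) cost[i, ] <- colSums(abs(t(geo_sig) - cand_sig[i, ]))
    asg <- solve_assignment(t(cost))  # row = geometry index, col = candidate
    ordered <- sel[asg$assignment]
    fit <- horn_absolute_orientation(geometry$centroids, pts[ordered, , drop = FALSE])
    list(selected = ordered, fit = fit)
  }
  direct <- fit_subset(active)
  if (direct$fit$fre <= fre_threshold) {
    return(list(status = "success", selected = direct$selected,
                transform = direct$fit$transform, fre = direct$fit$fre,
                residuals = direct$fit$residuals, stage = "direct"))
  }
  # stage 3 fallback: exhaustive 8-subsets of the best-scoring candidates
  score_all <- vapply(seq_len(n_all), function(i)
    sum(dist_matches_canon(dm[i, -i])), integer(1))
  pool <- order(-score_all, vol_dev, -intensity, label)[seq_len(min(n_all, max_exhaustive))]
  canon_sorted <- canon  # already sorted
  best <- NULL
  combos <- utils::combn(pool, 8L)
  for (k in seq_len(ncol(combos))) {
    sel <- combos[, k]
    dsub <- sort(dm[sel, sel][lower.tri(matrix(0, 8, 8))])
    if (max(abs(dsub - canon_sorted)) > tau) next  # cheap permutation-free reject
    cand <- fit_subset(sel)
    if (cand$fit$fre <= fre_threshold &&
        (is.null(best) || cand$fit$fre < best$fit$fre)) best <- cand
  }
  if (!is.null(best)) {
    return(list(status = "success", selected = best$selected,
                transform = best$fit$transform, fre = best$fit$fre,
                residuals = best$fit$residuals, stage = "exhaustive"))
  }
  status <- if (n_all == 8L) "high_residual" else "no_consistent_subset"
  list(status = status, fre = direct$fit$fre, n_candidates = n_all)
}
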