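scene_1mm <- render_test_scene()  # noiseless 3_15 CT at 1 mm slices

test_that("background suppression reports its threshold and rejects flat volumes", {
  sup <- suppress_background(scene_1mm$volume)
  expect_true(is.finite(attr(sup, "threshold")))
  expect_gt(attr(sup, "n_survivors"), 0)
  flat <- med_volume(array(7, c(5, 5, 5)), c(1, 1, 1))
  expect_error(suppress_background(flat), "no foreground")
})

test_that("raising the suppression percentile shrinks the survivor set", {
  set.seed(51)
  for (i in 1:5) {
    vol <- med_volume(array(rnorm(20^3, 100, 30), c(20, 20, 20)), c(1, 1, 1))
    lo <- suppress_background(vol, percentile = 0.9)
    hi <- suppress_background(vol, percentile = 0.99)
    surv_lo <- lo$voxels > min(lo$voxels)
    surv_hi <- hi$voxels > min(hi$voxels)
    expect_true(all(!surv_hi | surv_lo))  # hi-survivors are a subset
    expect_lte(sum(surv_hi), sum(surv_lo))
  }
})

test_that("edge response is zero on constant input, linear in intensity, and peaks on the shell", {
  flat <- med_volume(array(3, c(8, 8, 8)), c(1, 1, 1))
  expect_true(all(edge_response(flat, 3)$voxels == 0))
  e1 <- edge_response(scene_1mm$volume, 3)
  doubled <- scene_1mm$volume
  doubled$voxels <- doubled$voxels * 2
  e2 <- edge_response(doubled, 3)
  expect_equal(e2$voxels, 2 * e1$voxels, tolerance = 1e-9)
  # radial profile around one feature: maximal response near radius d/2
  single <- marker_geometry("iso", centroids = geo_ct$centroids,
                            feature_diameter = 5)
  sc <- render_marker_volume(single, rigid_transform(),
                             render_profile("CT", noise_sd = 0, blur_fwhm = 0.4),
                             spacing = c(0.5, 0.5, 0.5))
  e <- edge_response(sc$volume, 5)
  ctr <- sc$feature_centers[1, ]
  d <- dim(e$voxels)
  idx <- arrayInd(seq_along(e$voxels), d) - 1
  w <- voxel_to_world(e, idx)  # world coords of all voxels
  r <- sqrt(rowSums(sweep(w, 2, ctr)^2))
  near <- r < 5
  peak_r <- r[near][which.max(e$voxels[near])]
  expect_lt(abs(peak_r - 2.5), 0.75)
})

test_that("binarization labels the rendered features and added distractors", {
  sup <- suppress_background(scene_1mm$volume)
  edg <- edge_response(scene_1mm$volume, 3)
  cand <- binarize_and_label(sup, edg)
  expect_identical(nrow(cand), 8L)
  expect_true(all(cand$physical_volume ==
                    cand$voxel_count * voxel_volume(scene_1mm$volume)))
  # centroids within half a voxel diagonal of the truth
  truth <- scene_1mm$feature_centers
  for (i in seq_len(nrow(truth))) {
    d <- min(sqrt(rowSums(sweep(as.matrix(cand[, c("x", "y", "z")]), 2,
                                truth[i, ])^2)))
    expect_lt(d, 0.5 * voxel_diagonal(scene_1mm$volume))
  }
  # three distractor blobs -> eleven candidates
  noisy <- inject_distractors(scene_1mm$volume, 3, seed = 4,
                              avoid = scene_1mm$feature_centers)
  cand11 <- binarize_and_label(suppress_background(noisy),
                               edge_response(noisy, 3))
  expect_identical(nrow(cand11), 11L)
  expect_error(binarize_and_label(sup, edge_response(med_volume(
    array(0:1, c(4, 4, 4)), c(1, 1, 1)), 3)), "share one grid")
})

test_that("features closer than a voxel merge into one candidate", {
  two <- marker_geometry("3_15")$centroids[1:2, , drop = FALSE]
  two[2, ] <- two[1, ] + c(3.2, 0, 0)  # gap below one voxel at 1 mm spacing
  fake <- geo_ct
  fake$centroids[1:2, ] <- two
  sc <- render_marker_volume(fake, rigid_transform(),
                             render_profile("CT", noise_sd = 0),
                             spacing = c(1, 1, 1))
  cand <- binarize_and_label(suppress_background(sc$volume),
                             edge_response(sc$volume, 3))
  expect_identical(nrow(cand), 7L)  # 8 features, two merged
})

test_that("volume pruning applies the 0.6x lower and MRI-only 2x upper factors", {
  mk <- function(vols) {
    structure(data.frame(label_id = seq_along(vols), x = 0, y = 0, z = 0,
                         voxel_x = 0, voxel_y = 0, voxel_z = 0, voxel_count = 1L,
                         physical_volume = vols, mean_intensity = 1000),
              class = c("candidate_features", "data.frame"))
  }
  d3 <- marker_geometry("3_15")
  # cutoff 0.6 * (pi/6) * 27 = 8.482 mm^3
  kept <- prune_candidates_by_volume(mk(c(8.0, 8.49, 9.0)), d3, modality_profile("CT"))
  expect_identical(kept$label_id, c(2L, 3L))
  d6 <- marker_geometry("6_20")
  kept_mri <- prune_candidates_by_volume(mk(c(230, 100)), d6, modality_profile("MRI"))
  expect_identical(kept_mri$label_id, 2L)  # 230 > 2 * 113.097
  kept_ct <- prune_candidates_by_volume(mk(c(230, 100)), d6, modality_profile("CT"))
  expect_identical(kept_ct$label_id, c(1L, 2L))  # CT has no upper bound
})

test_that("detection recalls all eight features at thin and thick slices", {
  for (th in c(1, 5)) {
    sc <- render_test_scene(pose = rigid_transform(rotation_about_axis("z", 40),
                                                   c(3, 1, -2)), thickness = th)
    cand <- detect_candidates(sc$volume, geo_ct)
    expect_gte(nrow(cand), 8L)
    tol <- 0.5 * voxel_diagonal(sc$volume)
    for (i in 1:8) {
      d <- min(sqrt(rowSums(sweep(as.matrix(cand[, c("x", "y", "z")]), 2,
                                  sc$feature_centers[i, ])^2)))
      expect_lt(d, tol)
    }
    expect_true(is.list(attr(cand, "counts")))
  }
  air <- med_volume(array(0, c(30, 30, 20)) + rep(0, 30 * 30 * 20), c(1, 1, 1))
  expect_identical(nrow(detect_candidates(air, geo_ct)), 0L)
})

test_that("recall survives additive noise up to ten percent of the contrast", {
  contrast <- 3000 - 40
  ok <- 0L
  n_seeds <- 40L
  for (s in seq_len(n_seeds)) {
    sc <- render_test_scene(pose = random_rigid_transform(8, seed = 1000 + s),
                            noise_sd = 0.1 * contrast, seed = s)
    cand <- detect_candidates(sc$volume, geo_ct)
    hits <- sum(apply(sc$feature_centers, 1, function(p)
      min(sqrt(rowSums(sweep(as.matrix(cand[, c("x", "y", "z")]), 2, p)^2))) <
        0.5 * voxel_diagonal(sc$volume)))
    ok <- ok + (hits == 8L)
  }
  expect_identical(ok, n_seeds)
})
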