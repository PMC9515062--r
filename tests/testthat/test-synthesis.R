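test_that("rendered occupancy conserves the sphere volume", {
  prof <- render_profile("CT", noise_sd = 0, blur_fwhm = 0)
  sc <- render_marker_volume(geo_ct, rigid_transform(), prof, spacing = c(1, 1, 1))
  total <- sum(sc$volume$voxels - prof$background_intensity) /
    (prof$feature_intensity - prof$background_intensity) * voxel_volume(sc$volume)
  expect_equal(total, 8 * expected_feature_volume(geo_ct), tolerance = 0.02)
})

test_that("rendering is deterministic for a fixed seed", {
  a <- render_test_scene(noise_sd = 50, seed = 9)
  b <- render_test_scene(noise_sd = 50, seed = 9)
  expect_identical(a$volume$voxels, b$volume$voxels)
  c_ <- render_test_scene(noise_sd = 50, seed = 10)
  expect_false(identical(a$volume$voxels, c_$volume$voxels))
})

test_that("truncated features and bad spacings are rejected", {
  expect_error(render_marker_volume(geo_ct, rigid_transform(),
                                    render_profile("CT"),
                                    spacing = c(1, 1, 1), extent = c(40, 40, 10)),
               "truncated")
  expect_error(render_marker_volume(geo_ct, rigid_transform(),
                                    render_profile("CT"), spacing = c(1, -1, 1)),
               "positive")
})

test_that("phantom specs are point-symmetric with zero ideal dispersion", {
  for (spec in list(phantom_spec("plane"), phantom_spec("angle"),
                    phantom_spec("plane", orientation = random_rigid_transform(seed = 3)))) {
    stations <- t(sapply(spec$transforms, `[[`, "translation"))
    expect_equal(colMeans(stations), as.numeric(spec$symmetry_point),
                 tolerance = 1e-9)
    r <- sqrt(rowSums(sweep(stations, 2, spec$symmetry_point)^2))
    expect_equal(r, rep(100, 6), tolerance = 1e-9)
    expect_equal(stations[1:3, ] + stations[4:6, ],
                 matrix(2 * spec$symmetry_point, 3, 3, byrow = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
    for (nm in rownames(spec$virtual_targets))
      expect_lt(point_prediction_error(spec$transforms,
                                       spec$virtual_targets[nm, ]), 1e-9)
  }
  expect_error(phantom_spec("plane", tilt = 10), "tilt 0")
  # the angle phantom tilts each station toward the symmetry axis
  ang <- phantom_spec("angle", tilt = 30)
  expect_equal(ang$transforms[[1]]$rotation, rotation_about_axis("y", -30),
               tolerance = 1e-12)
})

test_that("the full render-localize-PPE loop stays below 0.3 mm at 1 mm slices", {
  spec <- phantom_spec("plane")
  ser <- make_phantom_series(spec, geo_ct, render_profile("CT", noise_sd = 0),
                             spacing = c(0.98, 0.98, 1))
  fits <- lapply(ser$volumes, localize_marker, geometry = geo_ct)
  expect_true(all(sapply(fits, `[[`, "status") == "success"))
  tr <- lapply(fits, `[[`, "transform")
  ppe <- point_prediction_error(tr, ser$virtual_targets["P100", ])
  expect_lt(ppe, 0.3)
})

test_that("distractor injection is seeded, separated and leaves n = 0 untouched", {
  sc <- render_test_scene(margin = 25)
  expect_identical(inject_distractors(sc$volume, 0)$voxels, sc$volume$voxels)
  a <- inject_distractors(sc$volume, 4, seed = 5, avoid = sc$feature_centers)
  b <- inject_distractors(sc$volume, 4, seed = 5, avoid = sc$feature_centers)
  expect_identical(a$voxels, b$voxels)
  centers <- attr(a, "distractor_centers")
  expect_identical(nrow(centers), 4L)
  for (i in seq_len(nrow(centers)))
    expect_gte(min(sqrt(rowSums(sweep(sc$feature_centers, 2, centers[i, ])^2))),
               2 * 4.5)
})

test_that("localization stays correct in the presence of distractor blobs", {
  ok <- 0L
  n_seeds <- 10L
  for (s in seq_len(n_seeds)) {
    sc <- render_test_scene(pose = random_rigid_transform(5, seed = 400 + s),
                            margin = 25, seed = s)
    vol <- inject_distractors(sc$volume, 4, seed = s, avoid = sc$feature_centers)
    fit <- localize_marker(vol, geo_ct)
    if (fit$status == "success" &&
        max(sqrt(rowSums((fitted(fit) - sc$feature_centers)^2))) < 1) ok <- ok + 1L
  }
  expect_identical(ok, n_seeds)
})

test_that("reslicing slab-averages with conserved intensity and identity at ratio 1", {
  sc <- render_test_scene(thickness = 1)
  vol <- sc$volume
  expect_identical(reslice(vol, 1)$voxels, vol$voxels)
  flat <- med_volume(array(42, c(6, 6, 10)), c(1, 1, 1))
  r5 <- reslice(flat, 5)
  expect_true(all(r5$voxels == 42))
  expect_equal(dim(r5$voxels)[3], 2L)
  prof <- render_profile("CT", noise_sd = 0)
  thick <- reslice(vol, 5)
  sum_orig <- sum(vol$voxels - prof$background_intensity) * voxel_volume(vol)
  sum_thick <- sum(thick$voxels - prof$background_intensity) * voxel_volume(thick)
  expect_equal(sum_thick, sum_orig, tolerance = 0.01)
  # world positions: resliced features localize near the originals
  fit <- localize_marker(thick, geo_ct)
  expect_identical(fit$status, "success")
  expect_lt(max(sqrt(rowSums((fitted(fit) - sc$feature_centers)^2))),
            0.5 * voxel_diagonal(thick))
  expect_error(reslice(vol, 0.5), "at least the current")
})
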