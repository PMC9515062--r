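test_that("Horn's method recovers constructed transforms exactly", {
  set.seed(61)
  s <- matrix(rnorm(24, sd = 30), 8)
  fit0 <- horn_absolute_orientation(s, s)
  expect_equal(as.matrix(fit0$transform), diag(4), tolerance = 1e-9)
  expect_lt(fit0$fre, 1e-12)
  tf <- rigid_transform(rotation_about_axis("z", 90), c(10, 0, 0))
  fit <- horn_absolute_orientation(s, transform_points(tf, s))
  expect_lt(max(abs(as.matrix(fit$transform) - as.matrix(tf))), 1e-9)
  expect_lt(fit$fre, 1e-9)
})

test_that("Horn residuals behave like the injected noise over many draws", {
  set.seed(62)
  n_seeds <- 1000L
  terr <- numeric(n_seeds); fres <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- matrix(rnorm(24, sd = 30), 8)
    tf <- rand_transform()
    tgt <- transform_points(tf, s) + matrix(rnorm(24, sd = 0.1), 8)
    fit <- horn_absolute_orientation(s, tgt)
    terr[i] <- sqrt(sum((fit$transform$translation - tf$translation)^2))
    fres[i] <- fit$fre
  }
  expect_lt(mean(terr), 0.15)
  expect_gt(mean(fres), 0.05)  # about the injected sd, reduced by the fit's dof
  expect_lt(mean(fres), 0.2)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(horn_absolute_orientation(line, line), "collinear")
  expect_error(horn_absolute_orientation(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  expect_error(horn_absolute_orientation(matrix(0, 3, 3), matrix(0, 4, 3)),
               "matched")
})

test_that("matching recovers the correct bijection from permuted exact points", {
  set.seed(63)
  for (i in 1:20) {
    tf <- rand_transform()
    pts <- transform_points(tf, geo_ct$centroids)
    perm <- sample(8)
    cand <- as_candidates(pts[perm, ], geo_ct)
    m <- match_candidates_to_geometry(cand, geo_ct, tau = 1, fre_threshold = 1)
    expect_identical(m$status, "success")
    expect_identical(m$selected, match(1:8, perm))  # candidate row of feature j
    expect_lt(m$fre, 1e-6)
  }
})

test_that("matching is invariant to candidate order and global rigid motion", {
  set.seed(64)
  tf <- rand_transform()
  pts <- transform_points(tf, geo_ct$centroids) + matrix(rnorm(24, sd = 0.05), 8)
  extra <- matrix(runif(12, -80, 80), 4)
  all_pts <- rbind(pts, extra)
  base <- match_candidates_to_geometry(as_candidates(all_pts, geo_ct), geo_ct,
                                       tau = 1, fre_threshold = 1)
  expect_identical(base$status, "success")
  sel_points <- all_pts[base$selected, ]  # matched point of each feature 1..8
  for (i in 1:5) {
    perm <- sample(nrow(all_pts))
    m <- match_candidates_to_geometry(as_candidates(all_pts[perm, ], geo_ct),
                                      geo_ct, tau = 1, fre_threshold = 1)
    expect_identical(m$status, "success")
    expect_equal(all_pts[perm, ][m$selected, ], sel_points,
                 tolerance = 1e-12, ignore_attr = TRUE)
    g <- rand_transform()
    moved <- transform_points(g, all_pts)
    mg <- match_candidates_to_geometry(as_candidates(moved, geo_ct), geo_ct,
                                       tau = 1, fre_threshold = 1)
    expect_identical(mg$status, "success")
    expect_identical(sort(mg$selected), sort(base$selected))
  }
})

test_that("an incomplete marker never passes as a wrong success", {
  set.seed(65)
  for (i in 1:100) {
    tf <- rand_transform()
    pts <- transform_points(tf, geo_ct$centroids)[1:7, ]  # one feature missing
    extra <- matrix(runif(9, -80, 80), 3)
    m <- match_candidates_to_geometry(as_candidates(rbind(pts, extra), geo_ct),
                                      geo_ct, tau = 1, fre_threshold = 1)
    expect_false(identical(m$status, "success"))
  }
  expect_identical(match_candidates_to_geometry(
    as_candidates(matrix(0, 3, 3), geo_ct), geo_ct)$status,
    "insufficient_candidates")
})

test_that("full localization recovers rendered poses within voxel-scale bounds", {
  pose <- rigid_transform(rotation_about_axis("z", 30) %*% rotation_about_axis("y", 20),
                          c(4, -6, 3))
  sc1 <- render_test_scene(pose = pose, thickness = 1)
  fit1 <- localize_marker(sc1$volume, geo_ct)
  expect_identical(fit1$status, "success")
  expect_lt(translation_error(fit1, pose), 0.3)
  expect_lt(rotation_error_deg(fit1, pose), 0.3)
  sc5 <- render_test_scene(pose = pose, thickness = 5)
  fit5 <- localize_marker(sc5$volume, geo_ct)
  expect_identical(fit5$status, "success")
  expect_lt(translation_error(fit5, pose), 1.0)
  air <- med_volume(array(rnorm(30^3, 0, 4), c(30, 30, 30)), c(1, 1, 1))
  expect_identical(localize_marker(air, geo_ct)$status, "insufficient_candidates")
})

test_that("the fitted-model accessors are consistent with the estimated pose", {
  sc <- render_test_scene(pose = rand_transform(5))
  fit <- localize_marker(sc$volume, geo_ct)
  expect_identical(fit$status, "success")
  m <- coef(fit)
  expect_identical(dim(m), c(4L, 4L))
  expect_equal(m[1:3, 1:3], fit$transform$rotation)
  p <- geo_ct$centroids
  expect_equal(predict(fit, p), transform_points(fit$transform, p))
  expect_equal(unname(fitted(fit)), unname(predict(fit, p)))
  r <- residuals(fit)
  expect_length(r, 8L)
  expect_equal(sqrt(mean(r^2)), fit$fre, tolerance = 1e-9)
  rv <- residuals(fit, type = "vector")
  expect_equal(unname(sqrt(rowSums(rv^2))), unname(r), tolerance = 1e-9)
  expect_output(print(summary(fit)), "per-feature residuals")
  failed <- localize_marker(med_volume(array(rnorm(20^3), c(20, 20, 20)), c(1, 1, 1)),
                            geo_ct)
  expect_error(coef(failed), "no pose estimated")
})
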