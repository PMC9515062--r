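make_int_volume <- function(dim = c(12, 10, 8), spacing = c(0.98, 0.98, 2),
                            origin = c(-5, 3, 10), direction = diag(3)) {
  set.seed(5)
  med_volume(array(sample.int(2000L, prod(dim), replace = TRUE), dim),
             spacing = spacing, origin = origin, direction = direction,
             modality = "CT")
}

test_that("voxel/world mapping follows the DICOM center-of-first-voxel convention", {
  vol <- make_int_volume()
  expect_equal(voxel_to_world(vol, c(0, 0, 0)), vol$origin, tolerance = 1e-12)
  v2 <- make_int_volume(spacing = c(1, 1, 4), origin = c(0, 0, 0))
  expect_equal(voxel_to_world(v2, c(1, 1, 1)), c(1, 1, 4), tolerance = 1e-12)
  set.seed(6)
  rvol <- make_int_volume(direction = rand_rotation())
  idx <- matrix(runif(300, -5, 20), ncol = 3)
  expect_lt(max(abs(world_to_voxel(rvol, voxel_to_world(rvol, idx)) - idx)), 1e-9)
})

test_that("med_volume validates spacing and direction", {
  arr <- array(0, c(4, 4, 4))
  expect_error(med_volume(arr, c(1, 0, 1)), "strictly positive")
  expect_error(med_volume(arr, c(1, 1, 1), direction = matrix(1, 3, 3)),
               "orthonormal")
  expect_error(med_volume(array(0, c(0, 4, 4)), c(1, 1, 1)), "non-empty")
})

test_that("MetaImage volumes round-trip exactly (.mha and .mhd + raw)", {
  dirn <- rand_rotation()
  vol <- make_int_volume(direction = dirn)
  for (ext in c(".mha", ".mhd")) {
    path <- file.path(withr::local_tempdir(), paste0("vol", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_equal(back$voxels, vol$voxels)
    expect_equal(back$spacing, vol$spacing, tolerance = 1e-12)
    expect_equal(back$origin, vol$origin, tolerance = 1e-12)
    expect_equal(back$direction, vol$direction, tolerance = 1e-12)
  }
  expect_error(write_volume(vol, tempfile(fileext = ".nii")), "MetaImage only")
})

test_that("MetaImage reader refuses missing spacing rather than defaulting", {
  path <- withr::local_tempfile(fileext = ".mha")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
               "ElementType = MET_UCHAR", "ElementDataFile = LOCAL"), path)
  con <- file(path, "ab"); writeBin(as.raw(1:8), con); close(con)
  expect_error(read_volume(path), "missing ElementSpacing")
})

test_that("NIfTI volumes are mapped from RAS into the LPS world frame", {
  arr <- array(runif(6 * 5 * 4), c(6, 5, 4))
  img <- RNifti::asNifti(arr)
  affine_ras <- structure(rbind(cbind(diag(c(1.5, 1.5, 3)), c(10, -20, 5)),
                                c(0, 0, 0, 1)), code = 2L)
  RNifti::sform(img) <- affine_ras
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  vol <- read_volume(path)
  expect_equal(dim(vol$voxels), dim(arr))
  expect_equal(vol$spacing, c(1.5, 1.5, 3), tolerance = 1e-5)
  # RAS origin (10, -20, 5) is LPS (-10, 20, 5)
  expect_equal(vol$origin, c(-10, 20, 5), tolerance = 1e-4)
  expect_equal(vol$voxels, arr, tolerance = 1e-6)
})

test_that("DICOM series round-trip with geometry, in any file order", {
  vol <- make_int_volume(dim = c(16, 14, 9), spacing = c(0.7, 0.9, 2.5),
                         origin = c(4, -7, 30))
  dir <- withr::local_tempdir()
  fidloc:::write_dicom_series(vol, dir)
  back <- read_volume(dir)
  expect_equal(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
  expect_equal(back$direction, vol$direction, tolerance = 1e-6)
  expect_identical(back$modality, "CT")
  # slice read order must not matter: shuffle file names
  files <- list.files(dir, full.names = TRUE)
  shuffled <- file.path(dir, sprintf("x_%s.dcm", rev(letters[seq_along(files)])))
  file.rename(files, shuffled)
  back2 <- read_volume(dir)
  expect_equal(back2$voxels, vol$voxels)
  expect_equal(back2$origin, vol$origin, tolerance = 1e-6)
})

test_that("a missing DICOM slice is detected as non-uniform spacing", {
  vol <- make_int_volume(dim = c(8, 8, 7))
  dir <- withr::local_tempdir()
  fidloc:::write_dicom_series(vol, dir, skip_slices = 4L)
  expect_error(read_volume(dir), "non-uniform slice spacing")
})

test_that("disagreeing DICOM spacing tags raise warnings, measured spacing wins", {
  vol <- make_int_volume(dim = c(8, 8, 6), spacing = c(1, 1, 2))
  dir <- withr::local_tempdir()
  fidloc:::write_dicom_series(vol, dir, spacing_tag = 3)
  expect_warning(back <- read_volume(dir), "SpacingBetweenSlices")
  expect_equal(back$spacing[3], 2, tolerance = 1e-9)
  dir2 <- withr::local_tempdir()
  fidloc:::write_dicom_series(vol, dir2, thickness = 5)
  expect_warning(back2 <- read_volume(dir2), "SliceThickness")
  expect_equal(back2$spacing[3], 2, tolerance = 1e-9)
})

test_that("rotated-grid and axis-aligned views of one scene agree in world space", {
  geo <- marker_geometry("3_15")
  pose <- rigid_transform(translation = c(0, 0, 0))
  prof <- render_profile("CT", noise_sd = 0)
  aligned <- render_marker_volume(geo, pose, prof, spacing = c(1, 1, 1))
  rot <- rotation_about_axis("z", 25)
  rotated <- render_marker_volume(geo, pose, prof, spacing = c(1, 1, 1),
                                  direction = rot)
  ca <- detect_candidates(aligned$volume, geo)
  cr <- detect_candidates(rotated$volume, geo)
  expect_identical(nrow(ca), 8L)
  expect_identical(nrow(cr), 8L)
  pa <- as.matrix(ca[order(ca$x, ca$y, ca$z), c("x", "y", "z")])
  pr <- as.matrix(cr[order(cr$x, cr$y, cr$z), c("x", "y", "z")])
  expect_lt(max(sqrt(rowSums((pa - pr)^2))), 0.5 * voxel_diagonal(c(1, 1, 1)))
})

test_that("unknown formats and missing files are refused", {
  expect_error(read_volume(tempfile(fileext = ".mha")), "not found")
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines("hello", p)
  expect_error(read_volume(p), "unsupported volume format")
})
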