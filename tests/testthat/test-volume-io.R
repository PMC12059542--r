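test_that("NRRD write/read round trip is the identity on data, spacing, origin", {
  v <- volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
              spacing = c(0.47, 0.47, 0.47), origin = c(-10, -10, 0))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(v, p)
  r <- read_volume(p)
  expect_identical(r$data, v$data)
  expect_identical(r$spacing, v$spacing)
  expect_identical(r$origin, v$origin)
})

test_that("NIfTI round trip preserves data exactly and geometry to header precision", {
  v <- volume(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
              spacing = c(0.47, 0.5, 0.6), origin = c(-10, -10, 0))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  r <- read_volume(p)
  expect_equal(r$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)
  # NIfTI stores geometry as float32
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
})

test_that("non-3D and unsupported inputs raise format errors", {
  p <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(1:20, 4)), p)
  expect_error(read_volume(p), class = "histocal_format_error")
  expect_error(read_volume("nope.xyz"), class = "histocal_format_error")
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               class = "histocal_format_error")
  expect_error(volume(array(c(NA, rep(1, 7)), c(2, 2, 2))),
               class = "histocal_format_error")
})

test_that("a synthetic phantom survives the NRRD round trip with its layer profile intact", {
  ph <- build_phantom(fixed_layer_spec(), rng_seed = 1, psf_sigma_mm = 0)
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(ph, p)
  r <- read_volume(p)
  prof_before <- apply(ph$data, 3, mean)
  prof_after <- apply(r$data, 3, mean)
  expect_identical(prof_after, prof_before)
})

test_that("crop retains exactly the voxels inside the box and preserves world coordinates", {
  v <- ramp_volume(5)
  # full-extent box is the identity
  e <- volume_extent(v)
  full <- crop(v, box_mm(e$lower - 0.1, e$upper + 0.1))
  expect_identical(full$data, v$data)
  expect_identical(full$origin, v$origin)
  # single-voxel box
  target <- index_to_world(v, c(2, 3, 1))
  one <- crop(v, box_mm(target - v$spacing / 2 + 1e-9,
                        target + v$spacing / 2 - 1e-9))
  expect_identical(dim(one$data), c(1L, 1L, 1L))
  expect_identical(one$data[1, 1, 1], v$data[3, 4, 2])
  # brute force: every retained voxel keeps its world coordinate
  box <- box_mm(c(-1.2, 0.5, 1.8), c(2.1, 3.1, 6.3))
  cr <- crop(v, box)
  for (i in seq_len(dim(cr$data)[1]))
    for (j in seq_len(dim(cr$data)[2]))
      for (k in seq_len(dim(cr$data)[3])) {
        w <- as.double(index_to_world(cr, c(i, j, k) - 1))
        expect_equal(as.double(sample_volume(v, w)), cr$data[i, j, k],
                     tolerance = 1e-9)
      }
  expect_error(crop(v, box_mm(c(100, 100, 100), c(101, 101, 101))),
               class = "histocal_empty_crop")
})

test_that("trilinear sampling is exact on linear fields and degrades to background outside", {
  v <- ramp_volume(7, coef = c(2, -3, 0.5), intercept = 7)
  # voxel centers
  w <- index_to_world(v, rbind(c(0, 0, 0), c(3, 2, 5)))
  expect_equal(as.double(sample_volume(v, w)),
               as.double(w %*% c(2, -3, 0.5) + 7), tolerance = 1e-12)
  # midpoint between two voxel centers along one axis
  mid <- index_to_world(v, c(2.5, 1, 1))
  expect_equal(as.double(sample_volume(v, mid)),
               mean(sample_volume(v, index_to_world(v, rbind(c(2, 1, 1), c(3, 1, 1))))),
               tolerance = 1e-12)
  # random interior points reproduce the analytic trilinear field
  set.seed(7)
  e <- volume_extent(v)
  pts <- sapply(1:3, function(a) runif(50, e$lower[a], e$upper[a]))
  expect_equal(as.double(sample_volume(v, pts)),
               as.double(pts %*% c(2, -3, 0.5) + 7), tolerance = 1e-9)
  # out of bounds -> background
  expect_identical(as.double(sample_volume(v, e$upper + 1)), 0)
  expect_identical(as.double(sample_volume(v, e$lower - 1, background = -5)), -5)
})

test_that("crop commutes with sampling at interior points", {
  v <- ramp_volume(7)
  box <- box_mm(c(-1.2, 0.5, 1.8), c(2.1, 3.1, 6.3))
  cr <- crop(v, box)
  set.seed(1)
  e <- volume_extent(cr)
  pts <- sapply(1:3, function(a) runif(20, e$lower[a] + 0.01, e$upper[a] - 0.01))
  expect_equal(as.double(sample_volume(cr, pts)),
               as.double(sample_volume(v, pts)), tolerance = 1e-12)
})

test_that("orientation codes are normalized on read (flipped axis round trips)", {
  # write a volume whose NIfTI sform flips X; reading must undo the flip
  arr <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(0.5, 0.5, 0.5)
  m <- diag(4)
  m[1, 1] <- -0.5; m[2, 2] <- 0.5; m[3, 3] <- 0.5
  m[1:3, 4] <- c(1, 0, 0)   # world X of index 0 is +1, decreasing
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  p <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(img, p)
  r <- read_volume(p)
  expect_equal(r$spacing, c(0.5, 0.5, 0.5), tolerance = 1e-6)
  expect_equal(r$origin[1], 1 - 0.5 * 2, tolerance = 1e-6)
  expect_equal(r$data, arr[3:1, , ], tolerance = 1e-12, ignore_attr = TRUE)
})
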