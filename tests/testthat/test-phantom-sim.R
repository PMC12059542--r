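test_that("the noiseless layer stack shows exactly five barium plateaus along Z", {
  spec <- fixed_layer_spec()
  ph <- build_phantom(spec, rng_seed = 1, psf_sigma_mm = 0)
  # restrict to the phantom XY footprint so water does not dilute the means
  box <- box_mm(c(-10, -10, -17), c(10, 10, 17))
  prof <- apply(crop(ph, box)$data, 3, mean)
  thr <- (spec$intensity_plain + spec$intensity_barium) / 2
  above <- prof > thr
  n_plateaus <- sum(diff(c(FALSE, above)) == 1)
  expect_identical(n_plateaus, 5L)
})

test_that("a crisp phantom takes exactly the three material intensities", {
  ph <- build_phantom(fixed_layer_spec(), rng_seed = 2, psf_sigma_mm = 0)
  expect_setequal(unique(as.vector(ph$data)), c(0, 15, 400))
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- build_phantom(small_phantom_spec(), rng_seed = 9)
  b <- build_phantom(small_phantom_spec(), rng_seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "layers"), attr(b, "layers"))
  c <- build_phantom(small_phantom_spec(), rng_seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("mixing strength follows the saturating closed form", {
  # the 20 s / 5 s mixing ratio matches the observed 122.9 / 52.5
  # intensity ratio of those treatment durations
  expect_equal(mixing_strength(20) / mixing_strength(5),
               (1 - exp(-20 / 11.6)) / (1 - exp(-5 / 11.6)), tolerance = 1e-12)
  expect_equal(mixing_strength(20) / mixing_strength(5), 122.9 / 52.5,
               tolerance = 0.01)
  # strictly increasing, saturating at m_max
  t <- seq(1, 60, by = 0.5)
  expect_true(all(diff(mixing_strength(t)) > 0))
  expect_equal(mixing_strength(1e6), 1, tolerance = 1e-12)
  expect_equal(mixing_strength(1e6, m_max = 0.7), 0.7, tolerance = 1e-12)
  expect_error(mixing_strength(0))
  expect_error(mixing_strength(-3))
})

test_that("treatment application has the no-op and full-mix limits", {
  ph <- build_phantom(fixed_layer_spec(), rng_seed = 3, psf_sigma_mm = 0.5)
  # zero mixing leaves the phantom untouched even with heterogeneity noise
  t0 <- treatment_spec(c(0, 0, 0), m_max = 0)
  expect_identical(apply_treatment(ph, t0, rng_seed = 1)$data, ph$data)
  # full mixing with no heterogeneity noise homogenizes the center voxel
  t1 <- treatment_spec(c(0, 0, 0), duration_s = 1e5, mix_noise_sd = 0,
                       barium_dilation = 1)
  post <- apply_treatment(ph, t1, rng_seed = 1)
  ctr_val <- as.double(sample_volume(post, c(0, 0, 0)))
  # independent homogenized value: mean of pre over the 10 mm Z window
  # within the ellipsoid XY footprint
  d <- dim(ph$data)
  w <- index_to_world(ph, as.matrix(expand.grid(i = 0:(d[1] - 1),
                                                j = 0:(d[2] - 1),
                                                k = 0:(d[3] - 1))) )
  inwin <- (w[, 1] / 2)^2 + (w[, 2] / 2)^2 <= 1 & abs(w[, 3]) <= 5
  expect_equal(ctr_val, mean(ph$data[inwin]), tolerance = 1e-9)
  expect_error(apply_treatment(ph, treatment_spec(c(0, 0, 100))))
})

test_that("treatment-zone contrast strictly increases with duration", {
  ph <- build_phantom(fixed_layer_spec(), rng_seed = 4)
  ctr <- c(0, 0, 0)
  radii <- c(2, 2, 4)
  d <- dim(ph$data)
  w <- index_to_world(ph, as.matrix(expand.grid(i = 0:(d[1] - 1),
                                                j = 0:(d[2] - 1),
                                                k = 0:(d[3] - 1))))
  inside <- colSums((t(w) - ctr)^2 / radii^2) <= 1
  mags <- vapply(c(5, 10, 15, 20), function(dur) {
    post <- apply_treatment(ph, treatment_spec(ctr, duration_s = dur),
                            rng_seed = 11)
    mean(abs(post$data - ph$data)[inside])
  }, 0)
  expect_true(all(diff(mags) > 0))
})

test_that("generated pairs are deterministic with localized, disjoint treatment signatures", {
  spec <- small_phantom_spec()
  tr <- treatment_spec(c(0, 0, 1))
  a <- generate_pair(spec, tr, quiet_noise(), rng_seed = 21)
  b <- generate_pair(spec, tr, quiet_noise(), rng_seed = 21)
  expect_identical(a$pre$data, b$pre$data)
  expect_identical(a$post$data, b$post$data)
  expect_identical(a$truth, b$truth)
  # noiseless, shift-free single treatment: the difference argmax falls
  # inside the ground-truth ellipsoid
  dif <- abs(a$post$data - a$pre$data)
  idx <- arrayInd(which.max(dif), dim(dif))
  wpk <- as.double(index_to_world(a$pre, idx - 1))
  expect_true(sum((wpk - c(0, 0, 1))^2 / c(2, 2, 4)^2) <= 1)
  # voxels outside the treatment support are untouched before shift/noise
  far <- abs(sweep(ramp_coords(a$pre), 2, c(0, 0, 1), `-`))
  untouched <- far[, 1] > 5 | far[, 2] > 5 | far[, 3] > 8
  expect_identical(a$post$data[array(untouched, dim(dif))],
                   a$pre$data[array(untouched, dim(dif))])
})

test_that("a four-cloud calibration pattern yields four disjoint difference components", {
  spec <- phantom_spec(size_mm = c(24, 46, 25), field_mm = c(32, 54, 33))
  pat <- calibration_pattern(c(0, -15, -1.5))
  # noiseless mixing so each zone is one solid blob at half maximum
  trs <- lapply(seq_len(4), function(k)
    treatment_spec(c(pat$targets$x[k], pat$targets$y[k], pat$targets$z[k]),
                   mix_noise_sd = 0))
  pair <- generate_pair(spec, trs, quiet_noise(), rng_seed = 31)
  dif <- abs(pair$post$data - pair$pre$data)
  # within a zone the change is bimodal (barium stripes change ~2.5x more
  # than plain layers), so the component threshold sits below the plain-
  # layer change to keep each zone connected while zones stay disjoint
  mask <- dif > max(dif) / 5
  labs <- histocal:::cpp_label3d(mask, dim(dif))
  expect_identical(max(labs), 4L)
  # overlapping treatments are rejected
  expect_error(generate_pair(spec, list(treatment_spec(c(0, 0, 0)),
                                        treatment_spec(c(1, 0, 0))),
                             quiet_noise(), rng_seed = 1),
               class = "histocal_overlap_error")
})

test_that("pre and post scans carry independent noise realizations", {
  spec <- small_phantom_spec()
  pair <- generate_pair(spec, treatment_spec(c(0, 0, 1)),
                        scan_noise_spec(shift_mm = c(0, 0, 0),
                                        rotation_deg = c(0, 0, 0)),
                        rng_seed = 5)
  # far from the treatment the difference is pure scan noise; it must not
  # cancel (same stream) nor explode (sd ~ sqrt(2) * sigma)
  resid <- (pair$post$data - pair$pre$data)[1:10, 1:10, 1:10]
  expect_gt(sd(resid), 8)          # > one stream's sigma
  expect_lt(sd(resid), 8 * 2)      # < twice
})
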