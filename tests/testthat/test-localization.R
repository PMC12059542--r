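# shared fixture: one small zero-shift scan pair and its difference image
loc_fixture <- local({
  pair <- generate_pair(small_phantom_spec(), treatment_spec(c(0, 0, 1)),
                        scan_noise_spec(shift_mm = c(0, 0, 0),
                                        rotation_deg = c(0, 0, 0)),
                        rng_seed = 101)
  tr <- register_rigid(fixed = pair$post, moving = pair$pre)
  pre_reg <- resample(pair$pre, tr, reference = pair$post)
  list(pair = pair, transform = tr,
       diff = difference_image(pre_reg, pair$post))
})

test_that("the difference image matches the truncated-Gaussian convolution oracle", {
  z <- volume(array(0, c(15, 15, 15)), spacing = rep(0.47, 3))
  expect_identical(unique(as.vector(difference_image(z, z)$data)), 0)
  # single impulse: center value is h times the normalized kernel weight
  h <- 12
  post <- z
  post$data[8, 8, 8] <- h
  d <- difference_image(z, post)
  w <- exp(-(-2:2)^2 / 2)
  g0 <- w[3] / sum(w)
  expect_equal(d$data[8, 8, 8], h * g0^3, tolerance = 1e-12)
  # direct separable convolution oracle at an off-center voxel
  expect_equal(d$data[7, 8, 9], h * (w[2] / sum(w)) * g0 * (w[2] / sum(w)),
               tolerance = 1e-12)
  expect_true(all(d$data >= 0))
  bad <- volume(array(0, c(15, 15, 14)), spacing = rep(0.47, 3))
  expect_error(difference_image(z, bad), class = "histocal_grid_mismatch")
})

test_that("the ROI mean cost has the constant and background limits", {
  v <- volume(array(3.7, c(20, 20, 20)), spacing = rep(0.47, 3))
  expect_equal(roi_mean_cost(v, volume_center(v), c(2, 2, 4)), 3.7,
               tolerance = 1e-12)
  expect_identical(roi_mean_cost(v, c(100, 100, 100), c(4, 4, 30)), 0)
})

test_that("XY optimization finds the mode of a separable bump from a distant seed", {
  sp <- rep(0.47, 3)
  n <- 61
  origin <- -(n - 1) * sp / 2
  ax <- origin[1] + (0:(n - 1)) * sp[1]
  ctr <- c(1.3, -0.9)
  gx <- exp(-(ax - ctr[1])^2 / (2 * 2^2))
  gy <- exp(-(ax - ctr[2])^2 / (2 * 2^2))
  gz <- exp(-ax^2 / (2 * 3^2))
  bump <- volume(100 * outer(outer(gx, gy), gz), spacing = sp, origin = origin)
  res <- optimize_xy(bump, seed_mm = c(ctr[1] - 2.1, ctr[2] + 2.1, 0))
  expect_equal3(res$xy_center_mm, ctr, tol = 0.25)
  # intensity scaling leaves the argmax unchanged
  bump5 <- bump
  bump5$data <- bump5$data * 5
  res5 <- optimize_xy(bump5, seed_mm = c(ctr[1] - 2.1, ctr[2] + 2.1, 0))
  expect_equal(res5$xy_center_mm, res$xy_center_mm, tolerance = 1e-9)
  expect_equal(res5$cost, 5 * res$cost, tolerance = 1e-9)
})

test_that("the Z profile equals the brute-force footprint average", {
  set.seed(42)
  v <- volume(array(runif(30 * 30 * 70, 0, 50), c(30, 30, 70)),
              spacing = rep(0.47, 3))
  xy <- c(7.2, 6.8)
  zc <- 15.5
  prof <- z_profile(v, xy, zc)
  p <- algo_params()
  sp <- v$spacing
  kxy <- floor((p$roi_dims_mm[1] / 6) / sp[1])
  kz <- floor((p$roi_dims_mm[3] / 2) / sp[3])
  expect_identical(nrow(prof), 2L * as.integer(kz) + 1L)
  manual <- vapply(seq(-kz, kz), function(iz) {
    acc <- 0
    for (ix in seq(-kxy, kxy)) for (iy in seq(-kxy, kxy))
      acc <- acc + sample_volume(v, c(xy[1] + ix * sp[1], xy[2] + iy * sp[2],
                                      zc + iz * sp[3]))
    acc / (2 * kxy + 1)^2
  }, 0)
  expect_equal(prof$intensity, manual, tolerance = 1e-9)
  # constant volume gives a constant profile
  cv <- volume(array(2, c(30, 30, 70)), spacing = rep(0.47, 3))
  expect_equal(unique(round(z_profile(cv, xy, zc)$intensity, 12)), 2)
})

test_that("the Z rule takes the boundary midpoint for wide clouds and the moment for narrow ones", {
  z0 <- 3.1
  z <- z0 + seq(-15, 15, by = 0.5)
  # 10 mm boxcar: crossings at the edges, midpoint at the center
  box <- tibble::tibble(z_mm = z, intensity = ifelse(abs(z - z0) <= 5, 7, 0))
  r <- locate_z(box)
  expect_equal(r$z_center_mm, z0, tolerance = 1e-9)
  expect_equal(r$z_extent_mm, 10, tolerance = 1e-9)
  expect_identical(r$z_method, "boundary_midpoint")
  # narrow Gaussian (FWHM 4 mm): weighted centroid, exact by symmetry
  sig <- 4 / (2 * sqrt(2 * log(2)))
  gauss <- tibble::tibble(z_mm = z, intensity = exp(-(z - z0)^2 / (2 * sig^2)))
  g <- locate_z(gauss)
  expect_identical(g$z_method, "weighted_centroid")
  expect_lt(abs(g$z_center_mm - z0), 0.1)
  expect_lt(g$z_extent_mm, 8)
  # constant profile: no sample exceeds the mean
  flat <- tibble::tibble(z_mm = z, intensity = rep(1, length(z)))
  expect_error(locate_z(flat), class = "histocal_degenerate_profile")
})

test_that("the Z branch rule agrees with an independent re-implementation on random profiles", {
  # straightforward oracle written from the rule description
  oracle <- function(z, v, thr_mm = 8) {
    m <- mean(v)
    top <- NA; bot <- NA
    for (i in seq_along(v)) if (v[i] > m) { top <- i; break }
    for (i in rev(seq_along(v))) if (v[i] > m) { bot <- i; break }
    ext <- z[bot] - z[top]
    if (ext >= thr_mm) list(zc = (z[top] + z[bot]) / 2, method = "boundary_midpoint")
    else {
      s <- top:bot
      list(zc = sum(z[s] * v[s]) / sum(v[s]), method = "weighted_centroid")
    }
  }
  set.seed(11)
  for (i in 1:50) {
    z <- seq(-15, 15, by = 0.47) + runif(1, -3, 3)
    width <- runif(1, 2, 14)
    c0 <- runif(1, -6, 6)
    v <- 5 * exp(-((z - c0) / (width / 2))^4) + runif(length(z), 0, 0.8)
    r <- locate_z(tibble::tibble(z_mm = z, intensity = v))
    o <- oracle(z, v)
    expect_identical(r$z_method, o$method)
    expect_equal(r$z_center_mm, o$zc, tolerance = 1e-12)
  }
})

test_that("a simulated single cloud is localized within the 1.5 mm equivalence margin", {
  pair <- loc_fixture$pair
  res <- localize_single(pair$pre, pair$post, seed_mm = c(0, 0, 1),
                         transform = loc_fixture$transform,
                         diff = loc_fixture$diff)
  expect_equal3(res$centroid_mm, c(0, 0, 1), tol = 1.5)
  expect_identical(nrow(res$seed_runs), 7L)
  expect_true(res$cost >= 0)
  # determinism of the whole chain
  res2 <- localize_single(pair$pre, pair$post, seed_mm = c(0, 0, 1),
                          transform = loc_fixture$transform,
                          diff = loc_fixture$diff)
  expect_identical(res2$centroid_mm, res$centroid_mm)
})

test_that("localization is equivariant under a common world-frame translation", {
  pair <- loc_fixture$pair
  res <- localize_single(pair$pre, pair$post, seed_mm = c(0, 0, 1))
  shift <- c(5, 5, 5)
  pre2 <- pair$pre;  pre2$origin <- pre2$origin + shift
  post2 <- pair$post; post2$origin <- post2$origin + shift
  res2 <- localize_single(pre2, post2, seed_mm = c(0, 0, 1) + shift)
  expect_equal3(res2$centroid_mm, res$centroid_mm + shift, tol = 1e-6)
})

test_that("the simplex does no worse than an exhaustive XY grid at grid resolution", {
  diff <- loc_fixture$diff
  res <- optimize_xy(diff, seed_mm = c(0, 0, 1))
  grid <- expand.grid(x = seq(-2, 2, length.out = 21),
                      y = seq(-2, 2, length.out = 21))
  costs <- vapply(seq_len(nrow(grid)), function(i)
    roi_mean_cost(diff, c(grid$x[i], grid$y[i], 1)), 0)
  expect_gte(res$cost, max(costs) - 1e-6 * max(costs))
})

test_that("the observed-center seed lands inside the true cloud", {
  seed <- find_observed_seed(loc_fixture$diff, near_mm = c(1.5, -1.5, 0))
  # the brightest voxel can sit anywhere in the (dilated) mixing zone
  expect_lt(abs(seed[1]), 3)
  expect_lt(abs(seed[2]), 3)
  expect_lt(abs(seed[3] - 1), 6.5)
})
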