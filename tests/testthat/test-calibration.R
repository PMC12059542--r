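# phantom sized for the 4-cloud pattern (10 mm Y steps)
pattern_phantom <- function() {
  phantom_spec(size_mm = c(24, 46, 25), field_mm = c(32, 54, 33))
}

make_session <- function(injected, noise, seed) {
  material <- build_phantom(pattern_phantom(), rng_seed = seed,
                            psf_sigma_mm = noise$psf_sigma_mm)
  zpos <- histocal:::layer_positions(material)
  pattern <- calibration_pattern(c(0, -15, zpos$on_layer - 1.5))
  targets <- histocal:::pattern_matrix(pattern)
  treated <- material
  for (k in seq_len(4))
    treated <- apply_treatment(treated, treatment_spec(targets[k, ] + injected),
                               rng_seed = seed + k)
  pre <- acquire_scan(material,
                      scan_noise_spec(noise_sigma = noise$noise_sigma,
                                      shift_mm = c(0, 0, 0),
                                      rotation_deg = c(0, 0, 0),
                                      psf_sigma_mm = noise$psf_sigma_mm),
                      rng_seed = seed + 11)
  post <- acquire_scan(treated, noise, rng_seed = seed + 12)
  list(pre = pre, post = post, pattern = pattern)
}

test_that("compute_offset is the difference of centroid averages", {
  pat <- calibration_pattern(c(0, -15, 0))
  targets <- histocal:::pattern_matrix(pat)
  expect_equal(compute_offset(targets, pat)$offset_mm, c(0, 0, 0))
  shifted <- sweep(targets, 2, c(1, -2, 0.5), `+`)
  r <- compute_offset(shifted, pat)
  expect_equal(r$offset_mm, c(1, -2, 0.5), tolerance = 1e-12)
  expect_equal(r$norm_mm, sqrt(sum(c(1, -2, 0.5)^2)), tolerance = 1e-12)
  # random sets against brute-force averaging
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rnorm(12, sd = 5), 4, 3)
    r <- compute_offset(m, pat)
    expect_equal(r$offset_mm,
                 c(mean(m[, 1]) - mean(targets[, 1]),
                   mean(m[, 2]) - mean(targets[, 2]),
                   mean(m[, 3]) - mean(targets[, 3])), tolerance = 1e-12)
  }
  expect_error(compute_offset(matrix(0, 3, 3), pat))
})

test_that("the calibration pattern has the fixed 10 mm Y / 1 mm Z spacing", {
  pat <- calibration_pattern(c(2, -15, -3))
  t <- pat$targets
  expect_equal(diff(t$y), rep(10, 3))
  expect_equal(diff(t$z), rep(1, 3))
  expect_equal(diff(t$x), rep(0, 3))
})

test_that("the joint estimator recovers an injected transducer offset within its spread", {
  # injected truth: the reference transducer's measured offset
  injected <- c(-1.5, -0.8, -1.5)
  ses <- make_session(injected, scan_noise_spec(), seed = 501)
  res <- localize_pattern(ses$pre, ses$post, ses$pattern)
  expect_equal3(res$offset_mm, injected, tol = 0.3)
  # offset identity: offset == avg measured - avg planned exactly
  expect_equal(res$offset_mm, res$avg_measured_mm - res$avg_planned_mm,
               tolerance = 1e-12)
  # pattern rigidity: measured centroids keep the pattern's exact shape
  dm <- diff(res$measured_mm)
  dp <- diff(res$planned_mm)
  expect_equal(dm %*% t(dm), dp %*% t(dp), tolerance = 1e-9)

  # the joint stage-2 optimum dominates the stage-1 average constrained
  # to the rigid pattern
  tr <- res$stages$transform
  pre_reg <- resample(ses$pre, tr, reference = ses$post)
  dif <- difference_image(pre_reg, ses$post)
  tinv <- invert_transform(tr)
  targets_post <- transform_points(tinv, res$planned_mm)
  measured_post <- transform_points(tinv, res$measured_mm)
  t0 <- res$stages$stage1_offset
  jc <- function(u3) mean(vapply(1:4, function(k)
    roi_mean_cost(dif, targets_post[k, ] + u3), 0))
  u_star <- measured_post[1, ] - targets_post[1, ]
  expect_gte(jc(c(u_star[1:2], t0[3])), jc(t0) - 1e-9)
})

test_that("the null case recovers a near-zero offset without noise", {
  ses <- make_session(c(0, 0, 0), quiet_noise(), seed = 601)
  res <- localize_pattern(ses$pre, ses$post, ses$pattern)
  expect_lt(res$norm_mm, 0.2)
  singles <- localize_pattern_single(ses$pre, ses$post, ses$pattern)
  expect_identical(nrow(singles), 4L)
  expect_lt(max(abs(c(singles$offset_x, singles$offset_y))), 0.35)
})

test_that("tidiers expose the offset result as tabular data", {
  pat <- calibration_pattern(c(0, -15, 0))
  r <- compute_offset(sweep(histocal:::pattern_matrix(pat), 2,
                            c(0.5, -1, 2), `+`), pat)
  td <- tidy(r)
  expect_identical(td$axis, c("x", "y", "z"))
  expect_equal(td$offset_mm, c(0.5, -1, 2), tolerance = 1e-12)
  gl <- glance(r)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$norm_mm, r$norm_mm)
})
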