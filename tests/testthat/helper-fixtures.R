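# Shared fixture builders.  Everything is generated in code at test time;
# the small phantom keeps the 0.47 mm pitch the algorithm's voxel-
# denominated constants assume while shrinking the field of view.

small_phantom_spec <- function(...) {
  phantom_spec(size_mm = c(22, 22, 25), field_mm = c(30, 30, 33), ...)
}

# deterministic layer stack with no manufacturing variability
fixed_layer_spec <- function(...) {
  phantom_spec(size_mm = c(22, 22, 25), field_mm = c(30, 30, 33),
               layer_thickness_mm = c(3.0, 1.1, 3.1, 1.0, 3.2, 1.2,
                                      3.0, 1.1, 3.1, 1.0, 3.2),
               layer_jitter_mm = 0, ...)
}

quiet_noise <- function(...) {
  scan_noise_spec(noise_sigma = 0, shift_mm = c(0, 0, 0),
                  rotation_deg = c(0, 0, 0), psf_sigma_mm = 0, ...)
}

# a small deterministic ramp volume f(x, y, z) = a x + b y + c z + d
ramp_volume <- function(n = 7, spacing = c(1, 0.8, 1.2),
                        origin = c(-2, 0, 1),
                        coef = c(2, -3, 0.5), intercept = 7) {
  idx <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  w <- cbind(origin[1] + idx$i * spacing[1],
             origin[2] + idx$j * spacing[2],
             origin[3] + idx$k * spacing[3])
  volume(array(w %*% coef + intercept, c(n, n, n)),
         spacing = spacing, origin = origin)
}

# isotropic Gaussian blob volume, smooth enough for resampling round trips
blob_volume <- function(n = 41, spacing = 0.5, sigma = 3, amp = 100) {
  sp <- rep(spacing, 3)
  origin <- -(n - 1) * sp / 2
  ax <- origin[1] + (0:(n - 1)) * spacing
  g <- exp(-ax^2 / (2 * sigma^2))
  volume(array(amp * outer(outer(g, g), g), c(n, n, n)),
         spacing = sp, origin = origin)
}

# n-by-3 matrix of world coordinates of every voxel center
ramp_coords <- function(v) {
  d <- dim(v$data)
  index_to_world(v, as.matrix(expand.grid(i = 0:(d[1] - 1),
                                          j = 0:(d[2] - 1),
                                          k = 0:(d[3] - 1))))
}

expect_equal3 <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("(%s) within %g of (%s)",
                              paste(signif(object, 4), collapse = ", "), tol,
                              paste(signif(expected, 4), collapse = ", ")))
}
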