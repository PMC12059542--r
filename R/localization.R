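#' Localization algorithm parameters
#'
#' Constants of the automated bubble-cloud localization algorithm.  The
#' voxel-denominated defaults assume the 0.47 mm reconstruction pitch:
#' a 5-voxel Gaussian kernel with 1-voxel SD smooths the absolute
#' difference image; the cost cuboid is 4 x 4 x 30 mm (slightly wider
#' than the nominal 4 mm cloud and ~3x its 8 mm height so every treated
#' layer is encompassed); the simplex is restarted from 7 perturbed seeds
#' (+/-2 voxels in X and Y, +/-4 voxels in Z); and the Z rule switches
#' from boundary midpoint to intensity-weighted centroid below an 8 mm
#' detected extent.
#'
#' @param gauss_kernel_vox odd Gaussian kernel size (voxels).
#' @param gauss_sigma_vox Gaussian SD (voxels).
#' @param roi_dims_mm cost cuboid dimensions (mm).
#' @param n_seeds number of simplex starts (7 = center + 2 in X + 2 in Y
#'   + 2 in Z).
#' @param seed_perturb_vox perturbation magnitudes (voxels) per axis.
#' @param z_threshold_mm extent (mm) at or above which the boundary
#'   midpoint is used for Z; below it the weighted centroid.
#' @param expected_cloud_mm nominal bubble-cloud size (mm), used by the
#'   visibility ellipsoid.
#' @param nm_maxit,nm_reltol Nelder-Mead budget and relative cost
#'   tolerance per start.
#' @return object of class `algo_params`.
#' @export
algo_params <- function(gauss_kernel_vox = 5L, gauss_sigma_vox = 1,
                        roi_dims_mm = c(4, 4, 30), n_seeds = 7L,
                        seed_perturb_vox = c(2, 2, 4), z_threshold_mm = 8,
                        expected_cloud_mm = c(4, 4, 8),
                        nm_maxit = 200L, nm_reltol = 1e-6) {
  stopifnot(gauss_kernel_vox >= 1, gauss_sigma_vox > 0,
            all(roi_dims_mm > 0), all(seed_perturb_vox > 0),
            z_threshold_mm > 0, all(expected_cloud_mm > 0))
  structure(list(gauss_kernel_vox = as.integer(gauss_kernel_vox),
                 gauss_sigma_vox = gauss_sigma_vox,
                 roi_dims_mm = as.double(roi_dims_mm),
                 n_seeds = as.integer(n_seeds),
                 seed_perturb_vox = as.double(seed_perturb_vox),
                 z_threshold_mm = z_threshold_mm,
                 expected_cloud_mm = as.double(expected_cloud_mm),
                 nm_maxit = as.integer(nm_maxit), nm_reltol = nm_reltol),
            class = "algo_params")
}

#' Gaussian-filtered absolute difference image
#'
#' `|post - pre|` followed by a separable Gaussian filter (default 5-voxel
#' kernel, 1-voxel SD per axis), the image in which treated layers appear
#' as bright mixing zones.  The two volumes must share a grid (i.e. the
#' pre volume has already been registered and resampled onto the post
#' grid).
#'
#' @param pre_registered pre-treatment [volume()] on the post grid.
#' @param post post-treatment [volume()].
#' @param params an [algo_params()].
#' @return the difference [volume()] (non-negative).
#' @export
difference_image <- function(pre_registered, post, params = algo_params()) {
  stopifnot_volume(pre_registered, "pre_registered")
  stopifnot_volume(post, "post")
  if (!identical(dim(pre_registered$data), dim(post$data)) ||
      max(abs(pre_registered$spacing - post$spacing)) > 1e-9 ||
      max(abs(pre_registered$origin - post$origin)) > 1e-9)
    abort("pre and post volumes are not on the same grid; register first.",
          class = "histocal_grid_mismatch")
  k <- gaussian_kernel_1d(params$gauss_kernel_vox, params$gauss_sigma_vox)
  d <- abs(post$data - pre_registered$data)
  out <- cpp_separable_blur(d, dim(d), k)
  volume(array(out, dim(d)), post$spacing, post$origin)
}

roi_lattice_offsets <- function(dims_mm, spacing) {
  lapply(1:3, function(a) {
    kk <- floor((dims_mm[a] / 2) / spacing[a])
    seq(-kk, kk) * spacing[a]
  })
}

# Closure evaluating the ROI mean cost with the sample lattice built once.
roi_cost_fun <- function(diff, dims_mm) {
  offs <- roi_lattice_offsets(dims_mm, diff$spacing)
  pts0 <- as.matrix(expand.grid(x = offs[[1]], y = offs[[2]], z = offs[[3]]))
  data <- diff$data; dm <- dim(data)
  sp <- diff$spacing; or <- diff$origin
  function(center_mm) {
    pts <- pts0
    pts[, 1] <- pts[, 1] + center_mm[1]
    pts[, 2] <- pts[, 2] + center_mm[2]
    pts[, 3] <- pts[, 3] + center_mm[3]
    mean(cpp_trilinear(data, dm, sp, or, pts, 0))
  }
}

#' Mean difference intensity over a cuboid ROI
#'
#' The localization cost: the mean of trilinear samples of the difference
#' image on a fixed lattice of pitch equal to the voxel spacing, spanning
#' the cuboid and anchored to its center (so the cost is continuous in
#' `center_mm`).  Samples falling outside the volume contribute the
#' background value 0.
#'
#' @param diff difference [volume()] from [difference_image()].
#' @param center_mm cuboid center, world mm.
#' @param dims_mm cuboid dimensions, mm (default the 4 x 4 x 30 cost
#'   cuboid).
#' @return scalar mean intensity.
#' @export
roi_mean_cost <- function(diff, center_mm, dims_mm = c(4, 4, 30)) {
  stopifnot_volume(diff, "diff")
  offs <- roi_lattice_offsets(dims_mm, diff$spacing)
  pts <- as.matrix(expand.grid(x = offs[[1]] + center_mm[1],
                               y = offs[[2]] + center_mm[2],
                               z = offs[[3]] + center_mm[3]))
  mean(sample_volume(diff, pts, background = 0))
}

#' Multi-start XY simplex optimization of the ROI cost
#'
#' Maximizes [roi_mean_cost()] over the cuboid's (X, Y) position with Z
#' held fixed per start, restarting the Nelder-Mead simplex from 7 seeds:
#' the unperturbed seed, +/-2 voxels in X, +/-2 voxels in Y, and +/-4
#' voxels in Z (the Z-perturbed starts guard against local optima; the
#' tall cuboid makes the cost only weakly Z-sensitive).  The winning run
#' is the one with the highest converged cost; ties break toward the
#' start nearest the unperturbed seed.
#'
#' @param diff difference [volume()].
#' @param seed_mm initial seed point, world mm (the observed or planned
#'   cloud center).
#' @param params an [algo_params()].
#' @return list with `xy_center_mm` (length 2), `z_mm` (the winning
#'   start's cuboid Z center), `cost`, `seed_runs` (tibble of all starts),
#'   and `improved` (FALSE when no run beat its starting cost).
#' @export
optimize_xy <- function(diff, seed_mm, params = algo_params()) {
  stopifnot_volume(diff, "diff")
  sp <- diff$spacing
  p <- params$seed_perturb_vox
  starts <- rbind(c(0, 0, 0),
                  c(-p[1] * sp[1], 0, 0), c(p[1] * sp[1], 0, 0),
                  c(0, -p[2] * sp[2], 0), c(0, p[2] * sp[2], 0),
                  c(0, 0, -p[3] * sp[3]), c(0, 0, p[3] * sp[3]))
  starts <- sweep(starts, 2, seed_mm, `+`)[seq_len(params$n_seeds), , drop = FALSE]
  cost_at <- roi_cost_fun(diff, params$roi_dims_mm)
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    z0 <- starts[i, 3]
    x0 <- starts[i, 1:2]
    # optimize the offset from the start so the initial simplex edge is
    # ~1 voxel regardless of where the seed sits in world space
    obj <- function(d) -cost_at(c(x0 + d, z0))
    start_cost <- -obj(c(0, 0))
    fit <- optim(c(0, 0), obj, method = "Nelder-Mead",
                 control = list(maxit = params$nm_maxit,
                                reltol = params$nm_reltol,
                                parscale = rep(10 * sp[1], 2)))
    runs[[i]] <- tibble(
      start_x = starts[i, 1], start_y = starts[i, 2], start_z = z0,
      x = x0[1] + fit$par[1], y = x0[2] + fit$par[2], cost = -fit$value,
      start_cost = start_cost,
      dist_to_seed = sqrt(sum((starts[i, ] - seed_mm)^2)),
      converged = fit$convergence == 0L)
  }
  runs <- dplyr::bind_rows(runs)
  best_cost <- max(runs$cost)
  cand <- which(runs$cost >= best_cost - 1e-9 * max(1, abs(best_cost)))
  win <- cand[which.min(runs$dist_to_seed[cand])]
  # improved == FALSE flags runs that could not beat their start (e.g.
  # seeded exactly at the optimum); the flag travels with the result
  improved <- best_cost > max(runs$start_cost) + 1e-12
  list(xy_center_mm = c(runs$x[win], runs$y[win]),
       z_mm = runs$start_z[win], cost = runs$cost[win],
       seed_runs = runs, improved = improved)
}

#' Z intensity profile through the ROI
#'
#' Averages the difference image over the central third of the cuboid's
#' XY footprint (a ~1.33 x 1.33 mm column) at each Z sample across the
#' full cuboid height, producing the 1D column vector scanned by
#' [locate_z()].  Sampling uses the same center-anchored lattice as
#' [roi_mean_cost()], pitch equal to the voxel spacing.
#'
#' @param diff difference [volume()].
#' @param xy_center_mm optimized (X, Y) cuboid center, mm.
#' @param z_center_mm cuboid Z center, mm.
#' @param params an [algo_params()].
#' @return tibble with columns `z_mm` (world Z of each sample) and
#'   `intensity`.
#' @export
z_profile <- function(diff, xy_center_mm, z_center_mm,
                      params = algo_params()) {
  stopifnot_volume(diff, "diff")
  dims <- params$roi_dims_mm
  foot <- roi_lattice_offsets(c(dims[1] / 3, dims[2] / 3, dims[3]),
                              diff$spacing)
  zs <- foot[[3]] + z_center_mm
  pts <- as.matrix(expand.grid(x = foot[[1]] + xy_center_mm[1],
                               y = foot[[2]] + xy_center_mm[2],
                               z = zs))
  v <- sample_volume(diff, pts, background = 0)
  nxy <- length(foot[[1]]) * length(foot[[2]])
  tibble(z_mm = zs,
         intensity = colMeans(matrix(v, nrow = nxy)))
}

#' Dual-rule Z localization from a column profile
#'
#' Scans the profile from both ends for the first sample exceeding the
#' profile mean; the span between those crossings is the detected cloud
#' extent.  At or above `z_threshold_mm` (8 mm, the expected cloud
#' height) the Z coordinate is the midpoint of the detected top and
#' bottom; below it -- the case of a cloud sitting between two barium
#' layers, where mixing does not delineate the cloud ends -- the
#' intensity-weighted centroid (first image moment) of the full profile
#' is used instead.
#'
#' @param profile tibble from [z_profile()] (columns `z_mm`, `intensity`).
#' @param params an [algo_params()].
#' @return list with `z_center_mm`, `z_extent_mm`, and `z_method`
#'   (`"boundary_midpoint"` or `"weighted_centroid"`).
#' @export
locate_z <- function(profile, params = algo_params()) {
  z <- profile$z_mm
  v <- profile$intensity
  if (length(v) == 0L) abort("empty Z profile.")
  thr <- mean(v)
  above <- which(v > thr)
  if (length(above) == 0L)
    abort("degenerate difference image: no Z sample exceeds the profile mean.",
          class = "histocal_degenerate_profile")
  z_top <- z[min(above)]
  z_bot <- z[max(above)]
  extent <- z_bot - z_top
  if (extent >= params$z_threshold_mm) {
    list(z_center_mm = (z_top + z_bot) / 2, z_extent_mm = extent,
         z_method = "boundary_midpoint")
  } else {
    # first moment over the detected span only: like the midpoint rule it
    # uses the bracketed cloud, so sub-threshold structure elsewhere in
    # the 30 mm window (e.g. an adjacent treatment zone) cannot drag the
    # centroid
    span <- seq(min(above), max(above))
    list(z_center_mm = sum(z[span] * v[span]) / sum(v[span]),
         z_extent_mm = extent, z_method = "weighted_centroid")
  }
}

# Localization stages downstream of registration, operating on a
# difference image; seed and result in the diff (post-scan) frame.
localize_in_diff <- function(diff, seed_mm, params = algo_params()) {
  xy <- optimize_xy(diff, seed_mm, params)
  prof <- z_profile(diff, xy$xy_center_mm, xy$z_mm, params)
  zres <- locate_z(prof, params)
  list(centroid_mm = c(xy$xy_center_mm, zres$z_center_mm),
       cost = roi_mean_cost(diff, c(xy$xy_center_mm, zres$z_center_mm),
                            params$roi_dims_mm),
       z_extent_mm = zres$z_extent_mm, z_method = zres$z_method,
       seed_runs = xy$seed_runs, improved = xy$improved, profile = prof)
}

#' Localize a single bubble-cloud treatment
#'
#' The full single-cloud pipeline: rigidly register the pre-treatment
#' scan to the post-treatment scan (MSE), compute the Gaussian-filtered
#' absolute difference image, maximize the cuboid-ROI mean intensity over
#' (X, Y) with multi-start Nelder-Mead, and resolve Z with the dual
#' boundary-midpoint / weighted-centroid rule.  The returned centroid is
#' expressed in the plan (pre-scan) world frame.
#'
#' @param pre pre-treatment [volume()] (plan frame).
#' @param post post-treatment [volume()].
#' @param seed_mm seed point in the plan frame (observed or planned cloud
#'   center), world mm.
#' @param params an [algo_params()].
#' @param transform optional precomputed [rigid_transform()] from
#'   [register_rigid]`(fixed = post, moving = pre)`; when supplied,
#'   registration is skipped.
#' @param diff optional precomputed difference [volume()] on the post
#'   grid (with `transform`), letting several seeds share one
#'   registration.
#' @return object of class `localization_result`: fields `centroid_mm`
#'   (plan frame), `centroid_post_mm`, `cost`, `z_extent_mm`, `z_method`,
#'   `seed_runs`, `transform`, `profile`.
#' @export
localize_single <- function(pre, post, seed_mm, params = algo_params(),
                            transform = NULL, diff = NULL) {
  if (is.null(transform)) {
    transform <- register_rigid(fixed = post, moving = pre)
  }
  if (is.null(diff)) {
    pre_reg <- resample(pre, transform, reference = post)
    diff <- difference_image(pre_reg, post, params)
  }
  # the difference image is attached to the result so further seeds can
  # reuse the registration (several clouds in one scan pair)
  # a plan-frame point p appears in the post frame at T^-1(p)
  tinv <- invert_transform(transform)
  seed_post <- as.double(transform_points(tinv, seed_mm))
  res <- localize_in_diff(diff, seed_post, params)
  centroid_plan <- as.double(transform_points(transform, res$centroid_mm))
  structure(list(centroid_mm = centroid_plan,
                 centroid_post_mm = res$centroid_mm,
                 cost = res$cost, z_extent_mm = res$z_extent_mm,
                 z_method = res$z_method, seed_runs = res$seed_runs,
                 improved = res$improved, transform = transform,
                 profile = res$profile, seed_mm = as.double(seed_mm)),
            class = "localization_result", diff = diff)
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> centroid (plan frame): (%s) mm\n",
              paste(sprintf("%.3f", x$centroid_mm), collapse = ", ")))
  cat(sprintf("  cost %.4g | Z extent %.2f mm | Z method: %s\n",
              x$cost, x$z_extent_mm, x$z_method))
  invisible(x)
}

#' @rdname localize_single
#' @param x a `localization_result`.
#' @param ... unused.
#' @export
tidy.localization_result <- function(x, ...) {
  dplyr::mutate(x$seed_runs, winner = .data$cost >= max(.data$cost) - 1e-12)
}

#' @rdname localize_single
#' @export
glance.localization_result <- function(x, ...) {
  tibble(x_mm = x$centroid_mm[1], y_mm = x$centroid_mm[2],
         z_mm = x$centroid_mm[3], cost = x$cost,
         z_extent_mm = x$z_extent_mm, z_method = x$z_method,
         improved = x$improved)
}

#' Coarse observed-center seed from a difference image
#'
#' Returns the world position of the brightest voxel of the difference
#' image within a window about `near_mm`, standing in for the operator's
#' manual seed at the observed cloud center (used when the planned
#' position may be several mm from the actual cloud, e.g. unknown
#' transducer offsets).
#'
#' @param diff difference [volume()].
#' @param near_mm window center, world mm.
#' @param window_mm full window size (mm) per axis.
#' @return length-3 world position (mm).
#' @export
find_observed_seed <- function(diff, near_mm, window_mm = c(14, 14, 18)) {
  stopifnot_volume(diff, "diff")
  box <- box_mm(near_mm - window_mm / 2, near_mm + window_mm / 2)
  sub <- crop(diff, box)
  idx <- arrayInd(which.max(sub$data), dim(sub$data))
  as.double(index_to_world(sub, idx - 1))
}
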