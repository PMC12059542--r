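#' Four-cloud calibration pattern
#'
#' The fixed multi-bubble-cloud treatment pattern: four planned centroids
#' `p_k = p0 + k * step` for `k = 0..3`, with the default step of 10 mm
#' in Y (unique phantom areas) and 1 mm in Z (each cloud samples a
#' different layer phase, since barium layers repeat every ~3-4 mm).
#'
#' @param p0_mm first planned centroid, world mm.
#' @param step_mm inter-cloud step (mm).
#' @param n number of clouds.
#' @return object of class `calibration_pattern` with a `targets` tibble.
#' @export
calibration_pattern <- function(p0_mm, step_mm = c(0, 10, 1), n = 4L) {
  p0_mm <- as.double(p0_mm)
  k <- seq_len(n) - 1L
  targets <- tibble(cloud = seq_len(n),
                    x = p0_mm[1] + k * step_mm[1],
                    y = p0_mm[2] + k * step_mm[2],
                    z = p0_mm[3] + k * step_mm[3])
  structure(list(targets = targets, step_mm = as.double(step_mm), n = as.integer(n)),
            class = "calibration_pattern")
}

pattern_matrix <- function(pattern) {
  as.matrix(pattern$targets[, c("x", "y", "z")])
}

#' Offset between measured and planned centroids
#'
#' The robot-to-bubble-cloud calibration offset: the component-wise mean
#' of the measured centroids minus the mean of the planned targets
#' (signed, per axis), with the Euclidean norm reported alongside.
#'
#' @param measured_mm n-by-3 matrix (or tibble with x, y, z) of measured
#'   centroids, plan-frame mm.
#' @param pattern a [calibration_pattern()] (or n-by-3 matrix of
#'   targets).
#' @param per_cloud optional list of per-cloud `localization_result`s to
#'   carry as diagnostics.
#' @return object of class `offset_result`: `offset_mm` (length 3),
#'   `norm_mm`, `avg_measured_mm`, `avg_planned_mm`, `per_cloud`.
#' @export
compute_offset <- function(measured_mm, pattern, per_cloud = NULL) {
  m <- as.matrix(as.data.frame(measured_mm))
  if (inherits(pattern, "calibration_pattern")) pattern <- pattern_matrix(pattern)
  p <- as.matrix(as.data.frame(pattern))
  if (!identical(nrow(m), nrow(p)))
    abort("measured and planned centroid counts differ.")
  avg_m <- colMeans(m)
  avg_p <- colMeans(p)
  off <- avg_m - avg_p
  structure(list(offset_mm = as.double(off),
                 norm_mm = sqrt(sum(off^2)),
                 avg_measured_mm = as.double(avg_m),
                 avg_planned_mm = as.double(avg_p),
                 measured_mm = m, planned_mm = p, per_cloud = per_cloud),
            class = "offset_result")
}

#' @export
print.offset_result <- function(x, ...) {
  cat(sprintf("<offset_result> offset (measured - planned): (%s) mm, |.| = %.3f mm\n",
              paste(sprintf("%.3f", x$offset_mm), collapse = ", "), x$norm_mm))
  invisible(x)
}

#' @rdname compute_offset
#' @param x an `offset_result`.
#' @param ... unused.
#' @export
tidy.offset_result <- function(x, ...) {
  tibble(axis = c("x", "y", "z"), offset_mm = x$offset_mm,
         avg_measured_mm = x$avg_measured_mm,
         avg_planned_mm = x$avg_planned_mm)
}

#' @rdname compute_offset
#' @export
glance.offset_result <- function(x, ...) {
  tibble(offset_x_mm = x$offset_mm[1], offset_y_mm = x$offset_mm[2],
         offset_z_mm = x$offset_mm[3], norm_mm = x$norm_mm)
}

#' Joint multi-bubble-cloud localization
#'
#' Localizes the four-cloud calibration pattern jointly, exploiting the
#' known inter-cloud spacing.  Stage 1 runs the single-cloud algorithm
#' seeded at each target (sharing one registration and difference image)
#' and averages the per-cloud deviations into an initial shared offset.
#' Stage 2 maximizes the mean ROI cost of all four cuboids moving
#' rigidly together over a shared (X, Y) offset (Nelder-Mead).  Stage 3
#' aligns the four Z profiles by the known 1 mm Z stagger, averages
#' them, and applies the unchanged dual Z rule to the averaged profile,
#' giving a shared Z offset.  The result is the average measured
#' centroid minus the average target.
#'
#' @param pre,post plan-frame pre scan and post scan [volume()]s.
#' @param pattern a [calibration_pattern()].
#' @param params an [algo_params()].
#' @param seed_mode `"observed"` seeds stage 1 at the brightest
#'   difference voxel near each target (the operator's "observed center"
#'   pick, robust to several-mm transducer offsets); `"plan"` seeds at
#'   the targets themselves.
#' @return an [compute_offset()] `offset_result`, with per-cloud stage-1
#'   results in `per_cloud` and stage diagnostics in `stages`.
#' @export
localize_pattern <- function(pre, post, pattern, params = algo_params(),
                             seed_mode = c("observed", "plan")) {
  seed_mode <- match.arg(seed_mode)
  transform <- register_rigid(fixed = post, moving = pre)
  pre_reg <- resample(pre, transform, reference = post)
  diff <- difference_image(pre_reg, post, params)
  tinv <- invert_transform(transform)
  targets <- pattern_matrix(pattern)
  n <- nrow(targets)
  targets_post <- transform_points(tinv, targets)
  # Stage 1: independent per-cloud localization
  stage1 <- vector("list", n)
  seeds_post <- targets_post
  ok <- TRUE
  for (k in seq_len(n)) {
    res <- tryCatch({
      sk <- targets_post[k, ]
      # window narrower than the 10 mm pattern spacing so a large
      # transducer offset cannot alias the pick onto a neighboring cloud
      if (seed_mode == "observed")
        sk <- find_observed_seed(diff, sk, window_mm = c(9.5, 9.5, 18))
      seeds_post[k, ] <- sk
      localize_single(pre, post, seed_mm = as.double(transform_points(transform, sk)),
                      params = params, transform = transform, diff = diff)
    }, error = function(e) e)
    if (inherits(res, "error")) { ok <- FALSE; stage1[[k]] <- NULL }
    else stage1[[k]] <- res
  }
  if (ok) {
    meas1_post <- do.call(rbind, lapply(stage1, function(r) r$centroid_post_mm))
    t0 <- colMeans(meas1_post - targets_post)
  } else {
    warn("stage-1 localization failed for at least one cloud; seeding the joint stage at zero offset.")
    t0 <- c(0, 0, 0)
  }
  # Stage 2: shared (X, Y) offset, ROIs rigidly co-moving
  cost_at <- roi_cost_fun(diff, params$roi_dims_mm)
  joint_cost <- function(u) {
    cents <- sweep(targets_post, 2, c(u[1], u[2], t0[3]), `+`)
    mean(vapply(seq_len(n), function(k) cost_at(cents[k, ]), 0))
  }
  fit <- optim(t0[1:2], function(u) -joint_cost(u), method = "Nelder-Mead",
               control = list(maxit = params$nm_maxit,
                              reltol = params$nm_reltol,
                              parscale = rep(10 * diff$spacing[1], 2)))
  u <- fit$par
  # Stage 3: shared Z via the average of stagger-aligned profiles
  profs <- lapply(seq_len(n), function(k)
    z_profile(diff, targets_post[k, 1:2] + u, targets_post[k, 3] + t0[3],
              params))
  avg_int <- rowMeans(do.call(cbind, lapply(profs, function(p) p$intensity)))
  # profile k is sampled about its own ROI center, so samples align in
  # the offset-from-center coordinate; express the average on cloud 1's
  # absolute axis
  avg_prof <- tibble(z_mm = profs[[1]]$z_mm, intensity = avg_int)
  zres <- locate_z(avg_prof, params)
  z_off <- zres$z_center_mm - targets_post[1, 3]
  measured_post <- sweep(targets_post, 2, c(u, z_off), `+`)
  measured_plan <- transform_points(transform, measured_post)
  out <- compute_offset(measured_plan, targets, per_cloud = stage1)
  out$stages <- list(transform = transform, stage1_offset = t0,
                     joint_cost = -fit$value, z_method = zres$z_method,
                     z_extent_mm = zres$z_extent_mm,
                     seeds_post = seeds_post)
  out
}

#' Per-cloud (single-cloud) offsets for a calibration session
#'
#' Localizes each pattern target independently with the single-cloud
#' algorithm (shared registration) and returns the per-cloud offsets
#' `measured - planned`, the estimator the joint pattern approach is
#' compared against.
#'
#' @inheritParams localize_pattern
#' @return tibble: cloud, axis-wise offsets (mm), cost, z_method.
#' @export
localize_pattern_single <- function(pre, post, pattern,
                                    params = algo_params(),
                                    seed_mode = c("observed", "plan")) {
  seed_mode <- match.arg(seed_mode)
  transform <- register_rigid(fixed = post, moving = pre)
  pre_reg <- resample(pre, transform, reference = post)
  diff <- difference_image(pre_reg, post, params)
  tinv <- invert_transform(transform)
  targets <- pattern_matrix(pattern)
  purrr::map_dfr(seq_len(nrow(targets)), function(k) {
    sk <- as.double(transform_points(tinv, targets[k, ]))
    if (seed_mode == "observed")
      sk <- find_observed_seed(diff, sk, window_mm = c(9.5, 9.5, 18))
    res <- localize_single(pre, post,
                           seed_mm = as.double(transform_points(transform, sk)),
                           params = params, transform = transform, diff = diff)
    tibble(cloud = k,
           offset_x = res$centroid_mm[1] - targets[k, 1],
           offset_y = res$centroid_mm[2] - targets[k, 2],
           offset_z = res$centroid_mm[3] - targets[k, 3],
           cost = res$cost, z_method = res$z_method)
  })
}
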