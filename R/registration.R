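#' Rigid (translation + rotation) world-space transform
#'
#' Parameterized by a translation (mm) and XYZ Euler angles (degrees)
#' applied about a fixed world-space `center` (mm).  A transform maps a
#' point `x` in the reference (fixed-volume) frame to the corresponding
#' point in the moving-volume frame:
#' `T(x) = R %*% (x - center) + center + translation`, with
#' `R = Rx(a) %*% Ry(b) %*% Rz(c)`.  This is the resampling convention:
#' `resample(moving, T, fixed)` pulls moving intensities onto the fixed
#' grid.
#'
#' @param translation numeric length-3, mm.
#' @param rotation numeric length-3, XYZ Euler angles in degrees.
#' @param center numeric length-3, world mm the rotation pivots about.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  structure(list(translation = as.double(translation),
                 rotation = as.double(rotation),
                 center = as.double(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, r = (%s) deg about (%s)\n",
              paste(signif(x$translation, 5), collapse = ", "),
              paste(signif(x$rotation, 5), collapse = ", "),
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

# Rotation matrix for XYZ Euler angles in degrees.
euler_to_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  rx %*% ry %*% rz
}

# Extract XYZ Euler angles (deg) from a rotation matrix; valid away from
# gimbal lock (|pitch| = 90 deg), far outside the small-angle regime used
# here.
matrix_to_euler <- function(m) {
  b <- asin(max(-1, min(1, m[1, 3])))
  a <- atan2(-m[2, 3], m[3, 3])
  c <- atan2(-m[1, 2], m[1, 1])
  c(a, b, c) * 180 / pi
}

#' Apply a rigid transform to world points
#' @param transform a [rigid_transform()].
#' @param points length-3 vector or n-by-3 matrix of world mm.
#' @return n-by-3 matrix of transformed points.
#' @export
transform_points <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  rot <- euler_to_matrix(transform$rotation)
  centered <- sweep(as.matrix(points), 2, transform$center, `-`)
  out <- centered %*% t(rot)
  sweep(out, 2, transform$center + transform$translation, `+`)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()] (same rotation center).
#' @export
invert_transform <- function(transform) {
  rot <- euler_to_matrix(transform$rotation)
  rinv <- t(rot)
  tinv <- -rinv %*% transform$translation
  rigid_transform(translation = as.double(tinv),
                  rotation = matrix_to_euler(rinv),
                  center = transform$center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`
#' to a point: `compose(first, second)(x) = second(first(x))`.  The
#' result pivots about `second`'s center.
#'
#' @param first,second [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transforms <- function(first, second) {
  r1 <- euler_to_matrix(first$rotation)
  r2 <- euler_to_matrix(second$rotation)
  r <- r2 %*% r1
  # affine offset of each: x -> R x + d with d = c + t - R c
  d1 <- first$center + first$translation - r1 %*% first$center
  d2 <- second$center + second$translation - r2 %*% second$center
  d <- r2 %*% d1 + d2
  cen <- second$center
  rigid_transform(translation = as.double(d + r %*% cen - cen),
                  rotation = matrix_to_euler(r), center = cen)
}

#' Resample a volume through a rigid transform
#'
#' Pulls `volume` intensities onto the grid of `reference`: the output
#' voxel at world position `x` takes the trilinearly interpolated value of
#' `volume` at `transform(x)`.  Out-of-bounds samples are filled with
#' `background`.
#'
#' @param volume the moving [volume()].
#' @param transform a [rigid_transform()] mapping reference-frame points
#'   into `volume`'s frame.
#' @param reference the [volume()] whose grid defines the output.
#' @param background fill value for unmapped voxels.
#' @return a [volume()] on `reference`'s grid.
#' @export
resample <- function(volume, transform, reference = volume, background = 0) {
  stopifnot_volume(volume)
  stopifnot_volume(reference, "reference")
  rot <- euler_to_matrix(transform$rotation)
  out <- cpp_resample_rigid(volume$data, dim(volume$data), volume$spacing,
                            volume$origin, dim(reference$data),
                            reference$spacing, reference$origin,
                            rot, transform$translation, transform$center,
                            as.double(background))
  volume(array(out, dim(reference$data)),
         spacing = reference$spacing, origin = reference$origin)
}

rigid_mse <- function(fixed, moving, par, center, stride = 1L) {
  rot <- euler_to_matrix(par[4:6])
  cpp_rigid_mse(fixed$data, dim(fixed$data), fixed$spacing, fixed$origin,
                moving$data, dim(moving$data), moving$spacing, moving$origin,
                rot, par[1:3], center, as.integer(stride))
}

downsample2 <- function(v) {
  d <- dim(v$data)
  out <- cpp_downsample2(v$data, d)
  nd <- (d + 1L) %/% 2L
  # block centers sit half a (new) voxel past the old first center
  volume(array(out, nd), spacing = v$spacing * 2,
         origin = v$origin + v$spacing / 2)
}

#' Rigid registration by mean-squared-error minimization
#'
#' Estimates the rigid transform `T` minimizing the mean squared intensity
#' difference between `fixed` and `moving` resampled through `T`, the
#' first stage of the bubble-cloud localization pipeline (it absorbs minor
#' physical shifts of the phantom in the water bath between scans).  The
#' optimization is a 3-level coarse-to-fine pyramid (4x, 2x, 1x block-mean
#' downsampling) with a derivative-free Nelder-Mead simplex at each level;
#' convergence at relative MSE change below `reltol` or `maxit` iterations
#' per level.  The MSE is evaluated over overlapping voxels only.
#'
#' @param fixed the fixed (target-frame) [volume()].
#' @param moving the moving [volume()].
#' @param init optional initial [rigid_transform()] (default identity).
#' @param levels number of pyramid levels (default 3).
#' @param maxit max simplex iterations per level.
#' @param reltol relative convergence tolerance on the cost.
#' @param stride integer voxel stride for MSE evaluation at the finest
#'   level (coarser levels always use stride 1).
#' @return a [rigid_transform()] mapping fixed-frame points to the moving
#'   frame, with a `diagnostics` attribute (final MSE, overlap voxel
#'   count, convergence flag per level).
#' @export
register_rigid <- function(fixed, moving, init = NULL, levels = 3L,
                           maxit = 200L, reltol = 1e-6, stride = 3L) {
  stopifnot_volume(fixed, "fixed")
  stopifnot_volume(moving, "moving")
  center <- volume_center(fixed)
  par <- if (is.null(init)) rep(0, 6) else c(init$translation, init$rotation)
  ov <- rigid_mse(fixed, moving, par, center)
  if (ov[2] < 0.5 * prod(dim(fixed$data)))
    abort("fixed and moving volumes overlap by less than 50% at the initial transform.",
          class = "histocal_degenerate_overlap")
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(levels - 1L)) {
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
  }
  # translation capture: exhaustive +/-2 mm grid on an extra-coarse level
  # seeds the simplex inside the basin of the global MSE minimum
  if (is.null(init)) {
    fc <- downsample2(pyr_f[[levels]]); mc <- downsample2(pyr_m[[levels]])
    grid <- as.matrix(expand.grid(tx = seq(-2, 2, by = 0.5),
                                  ty = seq(-2, 2, by = 0.5),
                                  tz = seq(-2, 2, by = 0.5)))
    costs <- vapply(seq_len(nrow(grid)), function(i)
      rigid_mse(fc, mc, c(grid[i, ], 0, 0, 0), center)[1], 0)
    par[1:3] <- grid[which.min(costs), ]
  }
  conv <- logical(0)
  budget <- pmin(c(100L, 300L, 400L), maxit * c(1L, 2L, 2L))
  for (l in rev(seq_len(levels))) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    st <- if (l == 1L) as.integer(stride) else 2L
    # optimize the offset from the incumbent so the initial simplex edge
    # is a fixed 0.1 mm / 0.05 deg regardless of the incumbent's size
    obj <- function(d) rigid_mse(f, m, par + d, center, st)[1]
    it <- budget[min(l, 3L)]
    fit <- optim(rep(0, 6), obj, method = "Nelder-Mead",
                 control = list(maxit = it, reltol = reltol,
                                parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
    par <- par + fit$par
    if (l == 1L) {
      # restart rebuilds the collapsed simplex around the incumbent
      fit <- optim(rep(0, 6), obj, method = "Nelder-Mead",
                   control = list(maxit = it, reltol = reltol,
                                  parscale = c(1, 1, 1, 0.5, 0.5, 0.5) / 5))
      par <- par + fit$par
    }
    conv <- c(conv, fit$convergence == 0L)
  }
  final <- rigid_mse(fixed, moving, par, center)
  out <- rigid_transform(translation = par[1:3], rotation = par[4:6],
                         center = center)
  attr(out, "diagnostics") <- list(
    mse = final[1], n_overlap = final[2], converged = conv,
    warning = if (!any(conv))
      "no pyramid level met the convergence tolerance; best iterate returned")
  out
}

#' Serialize / deserialize a rigid transform to JSON
#'
#' @param transform a [rigid_transform()].
#' @param path output (input) JSON path.
#' @return `path` invisibly; `read_transform` returns the transform.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(translation_mm = transform$translation,
                            rotation_deg = transform$rotation,
                            center_mm = transform$center,
                            convention = "xyz-euler-about-center"),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$translation_mm, x$rotation_deg, x$center_mm)
}
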