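#' 3D scalar volume with world geometry
#'
#' The universal image carrier used throughout histocal.  A `histo_volume`
#' bundles a 3D numeric array with its voxel spacing (mm/voxel) and world
#' origin (mm, position of the *center* of voxel `(0,0,0)` in 0-based index
#' convention).  World and index coordinates are related by
#' `world = origin + index * spacing`, component-wise; grids are always
#' axis-aligned.  Axis 3 of the array ("Z") is the layer-normal /
#' transducer axis.
#'
#' @param data numeric 3D array of voxel intensities (finite).
#' @param spacing numeric length-3, mm per voxel along x, y, z; all > 0.
#' @param origin numeric length-3, world mm of the first voxel center.
#' @return An object of class `histo_volume`.
#' @examples
#' v <- volume(array(0, c(4, 4, 4)), spacing = c(0.47, 0.47, 0.47))
#' dim(v)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort("`data` must be a 3D array.", class = "histocal_format_error")
  storage.mode(data) <- "double"
  spacing <- as.double(spacing)
  origin <- as.double(origin)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 strictly positive finite values (mm/voxel).",
          class = "histocal_format_error")
  if (length(origin) != 3L || !all(is.finite(origin)))
    abort("`origin` must be 3 finite values (mm).",
          class = "histocal_format_error")
  if (!all(is.finite(data)))
    abort("volume intensities must all be finite.",
          class = "histocal_format_error")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "histo_volume")
}

#' @export
dim.histo_volume <- function(x) dim(x$data)

#' @export
print.histo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<histo_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing: %s mm/voxel\n", paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin : (%s) mm\n", paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  range  : [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "histo_volume")

stopifnot_volume <- function(x, arg = "volume") {
  if (!is_volume(x))
    abort(sprintf("`%s` must be a histo_volume.", arg))
  invisible(x)
}

#' World extent of a volume
#'
#' Lower/upper world coordinates (mm) of the box spanned by the voxel
#' *centers* of a volume.
#'
#' @param volume a [volume()].
#' @return list with numeric `lower` and `upper` (length 3, mm).
#' @export
volume_extent <- function(volume) {
  stopifnot_volume(volume)
  list(lower = volume$origin,
       upper = volume$origin + (dim(volume$data) - 1) * volume$spacing)
}

#' World center of a volume (mm)
#' @param volume a [volume()].
#' @return numeric length-3.
#' @export
volume_center <- function(volume) {
  e <- volume_extent(volume)
  (e$lower + e$upper) / 2
}

#' Axis-aligned world-space box (mm)
#'
#' @param lower,upper numeric length-3 world coordinates with
#'   `upper > lower` component-wise.
#' @return list of class `histo_box`.
#' @export
box_mm <- function(lower, upper) {
  lower <- as.double(lower); upper <- as.double(upper)
  if (length(lower) != 3L || length(upper) != 3L || !all(upper > lower))
    abort("box must satisfy upper > lower component-wise.")
  structure(list(lower = lower, upper = upper), class = "histo_box")
}

#' Crop a volume to a world-space box
#'
#' Retains exactly the voxels whose centers fall inside `box` (the
#' "cropped about the phantom" step of the localization workflow).  The
#' origin is updated so world coordinates of retained voxels are
#' unchanged.
#'
#' @param volume a [volume()].
#' @param box a [box_mm()].
#' @return A cropped [volume()].
#' @export
crop <- function(volume, box) {
  stopifnot_volume(volume)
  if (!inherits(box, "histo_box")) abort("`box` must be a box_mm().")
  d <- dim(volume$data)
  idx <- lapply(1:3, function(a) {
    centers <- volume$origin[a] + (seq_len(d[a]) - 1) * volume$spacing[a]
    which(centers >= box$lower[a] & centers <= box$upper[a])
  })
  if (any(lengths(idx) == 0L))
    abort("crop box does not contain any voxel centers.",
          class = "histocal_empty_crop")
  volume(volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
         spacing = volume$spacing,
         origin = volume$origin + (vapply(idx, min, 1L) - 1) * volume$spacing)
}

#' Sample a volume at continuous world positions
#'
#' Trilinear interpolation at arbitrary world points (mm).  Points outside
#' the voxel-center extent return `background` rather than erroring, so
#' that ROI cuboids poking past a cropped volume edge degrade gracefully.
#'
#' @param volume a [volume()].
#' @param points numeric length-3 vector or n-by-3 matrix of world mm.
#' @param background value returned for out-of-bounds points (default 0).
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(volume, points, background = 0) {
  stopifnot_volume(volume)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) abort("`points` must have 3 columns (x, y, z mm).")
  cpp_trilinear(volume$data, dim(volume$data), volume$spacing, volume$origin,
                points, as.double(background))
}

#' Convert voxel indices (0-based) to world mm
#' @param volume a [volume()].
#' @param index numeric length-3 or n-by-3 0-based (possibly fractional).
#' @return matrix of world coordinates, n-by-3.
#' @export
index_to_world <- function(volume, index) {
  stopifnot_volume(volume)
  if (is.null(dim(index))) index <- matrix(index, ncol = 3, byrow = TRUE)
  sweep(sweep(index, 2, volume$spacing, `*`), 2, volume$origin, `+`)
}

#' Convert world mm to (continuous, 0-based) voxel indices
#' @param volume a [volume()].
#' @param world numeric length-3 or n-by-3 world mm.
#' @return matrix of continuous 0-based indices, n-by-3.
#' @export
world_to_index <- function(volume, world) {
  stopifnot_volume(volume)
  if (is.null(dim(world))) world <- matrix(world, ncol = 3, byrow = TRUE)
  sweep(sweep(world, 2, volume$origin, `-`), 2, volume$spacing, `/`)
}
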