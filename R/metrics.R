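#' Treatment-zone visibility
#'
#' Mean intensity of the Gaussian-filtered absolute difference image over
#' an axis-aligned ellipsoid of the nominal bubble-cloud size (default
#' 4 x 4 x 8 mm, i.e. radii 2 x 2 x 4 mm) placed at the observed cloud
#' center -- the per-trial visibility measure of the duration analysis.
#' The pair must already share a grid (registered); ellipsoid membership
#' is by voxel-center inclusion.
#'
#' @param pre registered pre-treatment [volume()].
#' @param post post-treatment [volume()] on the same grid.
#' @param center_mm ellipsoid center, world mm.
#' @param params an [algo_params()] (supplies the filter constants and
#'   `expected_cloud_mm`).
#' @return scalar mean intensity (arbitrary units).
#' @export
visibility <- function(pre, post, center_mm, params = algo_params()) {
  diff <- difference_image(pre, post, params)
  radii <- params$expected_cloud_mm / 2
  ext <- volume_extent(diff)
  if (any(center_mm - radii < ext$lower - 1e-9) ||
      any(center_mm + radii > ext$upper + 1e-9))
    abort("visibility ellipsoid extends outside the volume.")
  d <- dim(diff$data)
  ax <- lapply(1:3, function(a)
    ((diff$origin[a] + (seq_len(d[a]) - 1) * diff$spacing[a]) -
       center_mm[a]) / radii[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mean(diff$data[r2 <= 1])
}

#' Duration-group normalization of visibility records
#'
#' Removes the effect of treatment duration from per-trial visibility
#' measurements by subtracting, within each duration group, the pooled
#' mean over both treatment positions (on a barium layer vs. between
#' layers):
#' `A[i,j,k] = a[i,j,k] - (1/(2n)) * sum over k, i of a[i,j]`.
#' The formula assumes the groups are balanced (`n` trials per position
#' within every duration group); unbalanced input is an error.
#'
#' @param records data frame with columns `trial`, `duration_s`,
#'   `position_flag` (0 = between layers, 1 = on a layer), `intensity`.
#' @return the input tibble with a normalized intensity column `A`.
#' @export
normalize_visibility <- function(records) {
  records <- as_tibble(records)
  stopifnot(all(c("duration_s", "position_flag", "intensity") %in% names(records)))
  if (!all(records$position_flag %in% c(0, 1)))
    abort("`position_flag` must be 0 (between layers) or 1 (on a layer).")
  counts <- dplyr::count(records, .data$duration_s, .data$position_flag)
  if (length(unique(counts$n)) != 1L ||
      !all(table(counts$duration_s) == 2L))
    abort("unbalanced groups: each duration group needs n records for both positions.")
  dplyr::mutate(dplyr::group_by(records, .data$duration_s),
                A = .data$intensity - mean(.data$intensity)) |>
    dplyr::ungroup()
}

#' Mean residual error of measured vs. planned translations
#'
#' `MRE = (1/(J*n)) * sum over j, i of (d[i,j] - j)`: the signed mean of
#' (measured - planned) translation distances pooled over all planned
#' distances `j` and trials `i`.  Every planned distance must appear with
#' the same number of trials.  The result carries the pooled standard
#' deviation of the residuals and a per-distance summary.
#'
#' @param measurements data frame with columns `measured_mm` and
#'   `planned_mm` (one row per trial).
#' @param planned_levels planned distances that must all be present
#'   (default `1:6` mm).
#' @return object of class `mre_result` with `mre_mm`, `sd_mm`, `n`, and
#'   a `by_distance` tibble; `tidy()`/`glance()` methods available.
#' @export
mean_residual_error <- function(measurements, planned_levels = 1:6) {
  m <- as_tibble(measurements)
  stopifnot(all(c("measured_mm", "planned_mm") %in% names(m)))
  missing <- setdiff(planned_levels, unique(m$planned_mm))
  if (length(missing) > 0)
    abort(sprintf("missing planned translation group(s): %s mm.",
                  paste(missing, collapse = ", ")))
  resid <- m$measured_mm - m$planned_mm
  by_distance <- dplyr::summarise(
    dplyr::group_by(m, planned_mm = .data$planned_mm),
    n = dplyr::n(),
    mre_mm = mean(.data$measured_mm - .data$planned_mm),
    sd_mm = sd(.data$measured_mm - .data$planned_mm),
    .groups = "drop")
  structure(list(mre_mm = mean(resid), sd_mm = sd(resid), n = length(resid),
                 by_distance = by_distance),
            class = "mre_result")
}

#' @export
print.mre_result <- function(x, ...) {
  cat(sprintf("<mre_result> MRE = %.3f +/- %.3f mm (n = %d)\n",
              x$mre_mm, x$sd_mm, x$n))
  invisible(x)
}

#' @rdname mean_residual_error
#' @param x an `mre_result`.
#' @param ... unused.
#' @export
tidy.mre_result <- function(x, ...) x$by_distance

#' @rdname mean_residual_error
#' @export
glance.mre_result <- function(x, ...) {
  tibble(mre_mm = x$mre_mm, sd_mm = x$sd_mm, n = x$n)
}

#' Mean absolute deviation about the mean
#'
#' `MAD = (1/n) * sum |x_i - mean(x)|`, the replicate-variability metric
#' used to compare single- versus multi-cloud offset estimators (note:
#' mean absolute deviation about the arithmetic mean, not the
#' median-based estimator).
#'
#' @param x numeric vector of per-axis offsets (mm), length >= 2.
#' @return scalar MAD (mm).
#' @examples
#' mean_absolute_deviation(c(-1.4, -1.5, -1.5, -1.7))  # 0.0875
#' @export
mean_absolute_deviation <- function(x) {
  x <- as.double(x)
  if (length(x) < 2L || anyNA(x))
    abort("MAD needs at least 2 finite samples.")
  mean(abs(x - mean(x)))
}

#' Pearson product-moment correlation
#'
#' Textbook formula: the centered cross-product
#' `sum((x - mean(x)) * (y - mean(y)))` divided by the root product of
#' the centered sums of squares; used for the measured-versus-planned
#' translation agreement.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort("`x` and `y` must have equal length >= 3.")
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) abort("zero variance input.")
  sum(dx * dy) / sqrt(vx * vy)
}
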