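#' Experiment configuration
#'
#' Bundles the parameters of the four synthetic calibration experiments
#' (duration/visibility, translation accuracy, single-vs-multi MAD,
#' multi-transducer offset recovery).  Replicate counts default to the
#' study design (10 per planned translation, 4 calibration sessions, 6
#' sessions per transducer) and can be scaled down for quick runs.  A
#' fixed `rng_seed` makes every experiment fully reproducible: all
#' per-replicate seeds are derived from it.
#'
#' @param experiment one of `"duration"`, `"translation"`, `"mad"`,
#'   `"offsets"`.
#' @param n_replicates trials per cell (translation / duration designs).
#' @param n_sessions calibration sessions (mad / offsets designs).
#' @param durations_s treatment durations for the duration design (s).
#' @param translations_mm planned translations (mm).
#' @param axes axes exercised by the translation design.
#' @param injected_offset_mm fixed injected transducer offset for the
#'   MAD design (mm); default the reference transducer's measured offset.
#' @param injected_offsets_mm named list of injected offsets for the
#'   offsets design (one per simulated transducer).
#' @param rng_seed master integer seed.
#' @param phantom a [phantom_spec()].
#' @param scan_noise a [scan_noise_spec()].
#' @param algo an [algo_params()].
#' @param spacing_mm voxel pitch (mm).
#' @param output_dir optional directory for per-replicate CSV and summary
#'   JSON output; `NULL` writes nothing.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("translation", "mad", "duration",
                                             "offsets"),
                              n_replicates = 10L, n_sessions = 4L,
                              durations_s = c(5, 10, 15, 20, 25, 30),
                              translations_mm = 1:6,
                              axes = c("x", "y", "z"),
                              injected_offset_mm = c(-1.5, -0.8, -1.5),
                              injected_offsets_mm = list(
                                transducer1 = c(-1.1, -0.6, -3.3),
                                transducer2 = c(-0.1, 3.3, -2.1),
                                transducer3 = c(0.8, -4.3, -2.7),
                                transducer4 = c(-1.5, -0.9, -1.5)),
                              rng_seed = 1L,
                              phantom = phantom_spec(),
                              scan_noise = scan_noise_spec(),
                              algo = algo_params(),
                              spacing_mm = 0.47,
                              output_dir = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(n_replicates >= 1, n_sessions >= 1,
            length(durations_s) >= 1, length(translations_mm) >= 1,
            length(injected_offsets_mm) >= 1)
  structure(list(experiment = experiment,
                 n_replicates = as.integer(n_replicates),
                 n_sessions = as.integer(n_sessions),
                 durations_s = durations_s,
                 translations_mm = translations_mm, axes = axes,
                 injected_offset_mm = as.double(injected_offset_mm),
                 injected_offsets_mm = injected_offsets_mm,
                 rng_seed = as.integer(rng_seed), phantom = phantom,
                 scan_noise = scan_noise, algo = algo,
                 spacing_mm = spacing_mm, output_dir = output_dir),
            class = "experiment_config")
}

# Z (mm) of the barium layer center nearest `near`, and of the
# between-layer (plain) center nearest `near`, from phantom layer metadata.
layer_positions <- function(material, near = 0) {
  layers <- attr(material, "layers")
  mid <- (layers$z_lower + layers$z_upper) / 2
  bar <- layers$material == "barium"
  interior_plain <- !bar & layers$layer > 1 & layers$layer < nrow(layers)
  list(on_layer = mid[bar][which.min(abs(mid[bar] - near))],
       between = mid[interior_plain][which.min(abs(mid[interior_plain] - near))])
}

axis_unit <- function(axis) {
  switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
}

zero_shift <- function(noise) {
  noise$shift_mm <- c(0, 0, 0)
  noise$rotation_deg <- c(0, 0, 0)
  noise
}

write_report_files <- function(report, name, config) {
  dir <- config$output_dir
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$data, file.path(dir, paste0(name, "_replicates.csv")),
                   row.names = FALSE)
  jsonlite::write_json(report$summary, file.path(dir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

#' Translation-accuracy experiment
#'
#' The localization-accuracy design: per axis and planned distance (1-6
#' mm), a reference bubble cloud is created on a barium layer and a
#' second cloud at the planned translation along the tested axis plus a
#' fixed 10 mm lateral offset (the same non-overlap trick as the
#' calibration pattern, so adjacent treatments never merge).  One
#' pre/post scan pair brackets both treatments; both clouds are localized
#' from the shared registered difference image and the measured
#' translation is the signed component of the centroid difference along
#' the planned axis.  The report pools residuals into the per-axis mean
#' residual error (with SD) and the measured-vs-planned Pearson
#' correlation.
#'
#' @param config an [experiment_config()].
#' @return object of class `translation_report`: per-replicate `data`
#'   tibble, per-axis `summary` tibble, `config`.
#' @export
run_translation_experiment <- function(config = experiment_config("translation")) {
  cells <- expand.grid(axis = config$axes, planned = config$translations_mm,
                       trial = seq_len(config$n_replicates),
                       stringsAsFactors = FALSE)
  seeds <- derive_seeds(config$rng_seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    axis <- cells$axis[r]; planned <- cells$planned[r]; trial <- cells$trial[r]
    s <- derive_seeds(seeds[r], 2L)
    res <- tryCatch({
      material <- build_phantom(config$phantom, config$spacing_mm,
                                rng_seed = s[1],
                                psf_sigma_mm = config$scan_noise$psf_sigma_mm)
      zpos <- layer_positions(material)
      u <- axis_unit(axis)
      # 10 mm lateral separation perpendicular to the tested axis keeps
      # the adjacent clouds disjoint at every planned distance
      perp <- if (axis == "x") c(0, 10, 0) else c(10, 0, 0)
      ref_center <- c(-3, -5, zpos$on_layer)
      if (axis == "x") ref_center[1] <- -5
      mov_center <- ref_center + u * planned + perp
      pair <- generate_pair(config$phantom,
                            list(treatment_spec(ref_center),
                                 treatment_spec(mov_center)),
                            config$scan_noise, rng_seed = s[2],
                            spacing_mm = config$spacing_mm)
      ref_res <- localize_single(pair$pre, pair$post, seed_mm = ref_center,
                                 params = config$algo)
      mov_res <- localize_single(pair$pre, pair$post, seed_mm = mov_center,
                                 params = config$algo,
                                 transform = ref_res$transform,
                                 diff = attr(ref_res, "diff"))
      delta <- mov_res$centroid_mm - ref_res$centroid_mm
      tibble(axis = axis, planned_mm = planned, trial = trial,
             measured_mm = sum(delta * u),
             measured_norm_mm = sqrt(sum(delta^2)),
             ref_z_method = ref_res$z_method, mov_z_method = mov_res$z_method,
             ref_cost = ref_res$cost, mov_cost = mov_res$cost,
             seed = seeds[r], failed = FALSE, note = "")
    }, error = function(e) {
      tibble(axis = axis, planned_mm = planned, trial = trial,
             measured_mm = NA_real_, measured_norm_mm = NA_real_,
             ref_z_method = NA_character_, mov_z_method = NA_character_,
             ref_cost = NA_real_, mov_cost = NA_real_, seed = seeds[r],
             failed = TRUE, note = conditionMessage(e))
    })
    rows[[r]] <- res
  }
  data <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(data, !.data$failed)
  summary <- purrr::map_dfr(split(ok, ok$axis), function(d) {
    mre <- mean_residual_error(d, planned_levels = config$translations_mm)
    tibble(axis = d$axis[1], n = nrow(d), mre_mm = mre$mre_mm,
           sd_mm = mre$sd_mm,
           pearson_r = pearson_r(d$planned_mm, d$measured_mm),
           n_failed = config$n_replicates * length(config$translations_mm) - nrow(d))
  })
  report <- structure(list(data = data, summary = summary, config = config),
                      class = c("translation_report", "histocal_report"))
  write_report_files(report, "translation", config)
  report
}

# One simulated calibration session: phantom + 4-cloud pattern with the
# truth displaced by `injected_mm`; returns the multi-cloud offset and
# the four single-cloud offsets.
run_calibration_session <- function(config, injected_mm, rng_seed) {
  s <- derive_seeds(rng_seed, 3L)
  material <- build_phantom(config$phantom, config$spacing_mm, rng_seed = s[1],
                            psf_sigma_mm = config$scan_noise$psf_sigma_mm)
  zpos <- layer_positions(material)
  pattern <- calibration_pattern(c(0, -15, zpos$on_layer - 1.5))
  targets <- pattern_matrix(pattern)
  treatments <- lapply(seq_len(nrow(targets)), function(k)
    treatment_spec(targets[k, ] + injected_mm))
  treated <- material
  tseeds <- derive_seeds(s[3], nrow(targets) + 2L)
  for (k in seq_len(nrow(targets)))
    treated <- apply_treatment(treated, treatments[[k]], rng_seed = tseeds[k])
  pre <- acquire_scan(material, zero_shift(config$scan_noise),
                      rng_seed = tseeds[nrow(targets) + 1L])
  post <- acquire_scan(treated, config$scan_noise,
                       rng_seed = tseeds[nrow(targets) + 2L])
  multi <- localize_pattern(pre, post, pattern, params = config$algo)
  singles <- localize_pattern_single(pre, post, pattern, params = config$algo)
  list(multi = multi, singles = singles, pattern = pattern)
}

#' Single- versus multi-cloud variability experiment
#'
#' Simulates replicate calibration sessions (fresh phantom layers, fresh
#' scan noise, one fixed injected transducer offset), measures the offset
#' per session with both the joint four-cloud estimator and the four
#' independent single-cloud localizations, and reports the per-axis mean
#' absolute deviation of each estimator across sessions.
#'
#' @param config an [experiment_config()] (`n_sessions` sessions).
#' @return object of class `mad_report`: `data` (per session/estimator
#'   offsets), `summary` (per-axis MAD for both estimators), `config`.
#' @export
run_mad_experiment <- function(config = experiment_config("mad")) {
  seeds <- derive_seeds(config$rng_seed, config$n_sessions)
  rows <- vector("list", config$n_sessions)
  for (ses in seq_len(config$n_sessions)) {
    sess <- run_calibration_session(config, config$injected_offset_mm, seeds[ses])
    multi_row <- tibble(session = ses, estimator = "multi", cloud = NA_integer_,
                        offset_x = sess$multi$offset_mm[1],
                        offset_y = sess$multi$offset_mm[2],
                        offset_z = sess$multi$offset_mm[3],
                        seed = seeds[ses])
    single_rows <- dplyr::mutate(sess$singles, session = ses,
                                 estimator = "single", seed = seeds[ses])
    rows[[ses]] <- dplyr::bind_rows(
      multi_row, single_rows[, c("session", "estimator", "cloud",
                                 "offset_x", "offset_y", "offset_z", "seed")])
  }
  data <- dplyr::bind_rows(rows)
  summary <- purrr::map_dfr(split(data, data$estimator), function(d) {
    tibble(estimator = d$estimator[1], n = nrow(d),
           mad_x_mm = mean_absolute_deviation(d$offset_x),
           mad_y_mm = mean_absolute_deviation(d$offset_y),
           mad_z_mm = mean_absolute_deviation(d$offset_z),
           mean_x_mm = mean(d$offset_x), mean_y_mm = mean(d$offset_y),
           mean_z_mm = mean(d$offset_z))
  })
  report <- structure(list(data = data, summary = summary,
                           injected_offset_mm = config$injected_offset_mm,
                           config = config),
                      class = c("mad_report", "histocal_report"))
  write_report_files(report, "mad", config)
  report
}

#' Treatment-duration / visibility experiment
#'
#' Simulates single-cloud treatments at each duration, both on a barium
#' layer and between layers, measures the treatment-zone visibility, and
#' applies the duration-group normalization to contrast the two
#' positions.
#'
#' @param config an [experiment_config()] (`n_replicates` trials per
#'   duration and position).
#' @return object of class `duration_report`: per-trial `data` (with the
#'   normalized intensity `A`), `summary` per duration, and the
#'   between/on-layer contrast in `position_contrast`.
#' @export
run_duration_experiment <- function(config = experiment_config("duration")) {
  cells <- expand.grid(duration_s = config$durations_s, position_flag = c(0, 1),
                       trial = seq_len(config$n_replicates))
  seeds <- derive_seeds(config$rng_seed, nrow(cells))
  register <- !(identical(config$scan_noise$shift_mm, c(0, 0, 0)) &&
                  identical(config$scan_noise$rotation_deg, c(0, 0, 0)))
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    s <- derive_seeds(seeds[r], 4L)
    material <- build_phantom(config$phantom, config$spacing_mm, rng_seed = s[1],
                              psf_sigma_mm = config$scan_noise$psf_sigma_mm)
    zpos <- layer_positions(material)
    zc <- if (cells$position_flag[r] == 1) zpos$on_layer else zpos$between
    center <- c(0, 0, zc)
    treat <- treatment_spec(center, duration_s = cells$duration_s[r])
    treated <- apply_treatment(material, treat, rng_seed = s[2])
    pre <- acquire_scan(material, zero_shift(config$scan_noise), rng_seed = s[3])
    post <- acquire_scan(treated, config$scan_noise, rng_seed = s[4])
    if (register) {
      tr <- register_rigid(fixed = post, moving = pre)
      pre <- resample(pre, tr, reference = post)
      center <- as.double(transform_points(invert_transform(tr), center))
    }
    rows[[r]] <- tibble(trial = cells$trial[r],
                        duration_s = cells$duration_s[r],
                        position_flag = cells$position_flag[r],
                        intensity = visibility(pre, post, center, config$algo),
                        seed = seeds[r])
  }
  data <- normalize_visibility(dplyr::bind_rows(rows))
  summary <- dplyr::summarise(
    dplyr::group_by(data, duration_s = .data$duration_s),
    n = dplyr::n(), mean_intensity = mean(.data$intensity),
    sd_intensity = sd(.data$intensity), .groups = "drop")
  contrast <- dplyr::summarise(
    dplyr::group_by(data, position_flag = .data$position_flag),
    mean_A = mean(.data$A), sd_A = sd(.data$A), .groups = "drop")
  report <- structure(list(data = data, summary = summary,
                           position_contrast = contrast, config = config),
                      class = c("duration_report", "histocal_report"))
  write_report_files(report, "duration", config)
  report
}

#' Multi-transducer offset-recovery experiment
#'
#' For each simulated transducer (a fixed injected 3D offset), runs
#' `n_sessions` calibration sessions with the joint four-cloud estimator
#' and reports the per-axis median and interquartile range of the
#' recovered offsets, plus the recovery error against the injection.
#'
#' @param config an [experiment_config()] with at least two entries in
#'   `injected_offsets_mm`.
#' @return object of class `offsets_report`: per-session `data`,
#'   per-transducer-axis `summary`, `config`.
#' @export
run_offsets_experiment <- function(config = experiment_config("offsets")) {
  if (length(config$injected_offsets_mm) < 2L)
    abort("the offsets design needs at least two injected transducer offsets.")
  tnames <- names(config$injected_offsets_mm) %||%
    paste0("transducer", seq_along(config$injected_offsets_mm))
  rows <- list()
  for (t in seq_along(config$injected_offsets_mm)) {
    inj <- as.double(config$injected_offsets_mm[[t]])
    seeds <- derive_seeds(config$rng_seed + 131 * t, config$n_sessions)
    for (ses in seq_len(config$n_sessions)) {
      sess <- run_calibration_session(config, inj, seeds[ses])
      rows[[length(rows) + 1L]] <-
        tibble(transducer = tnames[t], session = ses,
               injected_x = inj[1], injected_y = inj[2], injected_z = inj[3],
               offset_x = sess$multi$offset_mm[1],
               offset_y = sess$multi$offset_mm[2],
               offset_z = sess$multi$offset_mm[3], seed = seeds[ses])
    }
  }
  data <- dplyr::bind_rows(rows)
  long <- tidyr::pivot_longer(data,
                              cols = c("offset_x", "offset_y", "offset_z"),
                              names_to = "axis", names_prefix = "offset_",
                              values_to = "offset_mm")
  long$injected_mm <- dplyr::case_when(
    long$axis == "x" ~ long$injected_x,
    long$axis == "y" ~ long$injected_y,
    TRUE ~ long$injected_z)
  summary <- dplyr::summarise(
    dplyr::group_by(long, transducer = .data$transducer, axis = .data$axis),
    n = dplyr::n(),
    injected_mm = .data$injected_mm[1],
    median_mm = median(.data$offset_mm),
    iqr_mm = stats::IQR(.data$offset_mm),
    bias_mm = mean(.data$offset_mm) - .data$injected_mm[1],
    .groups = "drop")
  report <- structure(list(data = data, summary = summary, config = config),
                      class = c("offsets_report", "histocal_report"))
  write_report_files(report, "offsets", config)
  report
}

#' @export
print.histocal_report <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1]))
  print(x$summary)
  invisible(x)
}
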