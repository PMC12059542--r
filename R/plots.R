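#' Plot a translation-accuracy report
#'
#' Strip plot of measured versus planned translation per axis, with the
#' per-distance mean and the identity diagonal (perfect agreement).
#'
#' @param object a `translation_report` from
#'   [run_translation_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.translation_report <- function(object, ...) {
  d <- dplyr::filter(object$data, !.data$failed)
  means <- dplyr::summarise(
    dplyr::group_by(d, .data$axis, .data$planned_mm),
    measured_mm = mean(.data$measured_mm), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$planned_mm, y = .data$measured_mm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey50") +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = means, shape = 18, size = 3, color = "#2166ac") +
    ggplot2::facet_wrap(~axis, nrow = 1) +
    ggplot2::labs(x = "planned translation (mm)",
                  y = "measured translation (mm)",
                  title = "Measured vs. planned bubble-cloud translations") +
    ggplot2::theme_minimal()
}

#' Plot a duration/visibility report
#'
#' Box plot of treatment-zone visibility by treatment duration.
#'
#' @param object a `duration_report` from [run_duration_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.duration_report <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = factor(.data$duration_s),
                               y = .data$intensity)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = "treatment duration (s)",
                  y = "mean |difference| intensity in treatment zone",
                  title = "Treatment-zone visibility vs. duration") +
    ggplot2::theme_minimal()
}

#' Plot a MAD comparison report
#'
#' Per-axis offsets of the single- and multi-cloud estimators across
#' sessions; tighter multi-cloud spread reproduces the variability
#' reduction of the joint estimator.
#'
#' @param object a `mad_report` from [run_mad_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mad_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data,
                              cols = c("offset_x", "offset_y", "offset_z"),
                              names_to = "axis", names_prefix = "offset_",
                              values_to = "offset_mm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$estimator,
                                     y = .data$offset_mm)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "measured offset (mm)",
                  title = "Single- vs. multi-cloud offset variability") +
    ggplot2::theme_minimal()
}

#' Plot a multi-transducer offsets report
#'
#' Recovered per-axis offsets per simulated transducer, with the
#' injected truth marked.
#'
#' @param object an `offsets_report` from [run_offsets_experiment()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.offsets_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$data,
                              cols = c("offset_x", "offset_y", "offset_z"),
                              names_to = "axis", names_prefix = "offset_",
                              values_to = "offset_mm")
  inj <- tidyr::pivot_longer(
    dplyr::distinct(object$data, .data$transducer, .data$injected_x,
                    .data$injected_y, .data$injected_z),
    cols = c("injected_x", "injected_y", "injected_z"),
    names_to = "axis", names_prefix = "injected_", values_to = "offset_mm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$transducer,
                                     y = .data$offset_mm)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = inj, shape = 4, size = 3, color = "#b2182b") +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "recovered offset (mm)",
                  title = "Transducer offset recovery (x = injected truth)") +
    ggplot2::theme_minimal()
}
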