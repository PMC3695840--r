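#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a single-replicate trajectory
#'
#' @param object An `nfkb_trajectory` tibble.
#' @param species Species to show (default nuclear NF-kB).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nfkb_trajectory <- function(object, species = "NFkBn", ...) {
  df <- trajectory_long(object)
  df <- df[df$species %in% species, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "time after stimulation (h)",
                  y = "concentration (µM)")
}

#' Trajectory fan of an ensemble with its SE average
#'
#' Individual replicate curves with the equal-weight ensemble average
#' overlaid, the standard way of looking at single-cell heterogeneity
#' against the population-level response.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param species Species column (default `"NFkBn"`).
#' @param max_curves Cap on the number of individual curves drawn
#'   (default 100).
#' @return A ggplot.
#' @export
plot_ensemble <- function(ensemble, species = "NFkBn", max_curves = 100) {
  stopifnot("trajectory" %in% names(ensemble))
  idx <- which(ensemble$ok)
  idx <- idx[seq_len(min(length(idx), max_curves))]
  fan <- dplyr::bind_rows(lapply(idx, function(i) {
    tr <- ensemble$trajectory[[i]]
    tibble::tibble(replicate = ensemble$replicate[i],
                   time_h = tr$time_h, value = tr[[species]])
  }))
  avg <- ensemble_average(ensemble, species)
  ggplot2::ggplot(fan, ggplot2::aes(.data$time_h, .data$value,
                                    group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.2, colour = "steelblue") +
    ggplot2::geom_line(data = avg, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "time after stimulation (h)",
                  y = paste0(species, " (µM)"))
}

#' Plot a dose-response curve
#'
#' @param object An `nfkb_dose_response` tibble.
#' @param ... Unused.
#' @return A ggplot (log-log, forward and backward sweeps).
#' @export
autoplot.nfkb_dose_response <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("forward",
                                                         "backward"),
                            names_to = "sweep", values_to = "level")
  df <- df[df$TR > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$TR, .data$level,
                                   colour = .data$sweep)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "TR (dosage)",
                  y = "quasi-steady-state NFkBn (µM)")
}

#' Histograms of the six dynamic features
#'
#' @param features An [ensemble_features()] tibble.
#' @param bins Histogram bins (default 50).
#' @return A ggplot faceted by feature.
#' @export
plot_feature_distributions <- function(features, bins = 50) {
  keep <- c("first_maximum", "first_translocation_time", "first_period",
            "ratio_first_min_to_first_max",
            "ratio_second_max_to_first_max",
            "ratio_steady_state_to_first_max")
  df <- tidyr::pivot_longer(features[, keep], dplyr::everything(),
                            names_to = "feature", values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "replicates")
}

#' Bar graph of the dynamic-pattern fractions
#'
#' @param patterns A [pattern_distribution()] tibble (or a list of them
#'   named by condition).
#' @return A ggplot.
#' @export
plot_pattern_fractions <- function(patterns) {
  if (!is.data.frame(patterns)) {
    patterns <- dplyr::bind_rows(patterns, .id = "condition")
  }
  p <- ggplot2::ggplot(patterns,
                       ggplot2::aes(.data$pattern, .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of replicates") +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
  if ("condition" %in% names(patterns)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}
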