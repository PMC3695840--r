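#' Settings for peak detection, feature extraction and pattern classification
#'
#' The conventions behind the trajectory analytics, exposed because pattern
#' fractions are sensitive to them. A local maximum counts as a peak when
#' its amplitude is at least `amplitude_floor` and its prominence (height
#' above the higher of the two neighbouring valleys) is at least
#' `prominence_frac` times the global maximum of the series; this keeps
#' small wiggles on a decaying tail from registering as oscillation peaks.
#' A trajectory with at least `min_peaks_sustained` peaks whose
#' second-to-first peak amplitude ratio is at least `sustain_threshold` is
#' classified as a sustained oscillation.
#'
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   series global maximum (default 0.05).
#' @param amplitude_floor Minimum peak amplitude in concentration units
#'   (default `1e-4 * 0.06`, i.e. 1e-4 of total NF-kB).
#' @param sustain_threshold Second/first peak amplitude ratio separating
#'   sustained from damped oscillations (default 0.6).
#' @param min_peaks_sustained Minimum number of detected peaks for a
#'   sustained oscillation (default 3).
#' @param steady_window Final fraction of the simulated window averaged to
#'   estimate the steady state (default 0.1).
#' @return A list of class `nfkb_settings`.
#' @export
feature_settings <- function(prominence_frac = 0.05,
                             amplitude_floor = 1e-4 * 0.06,
                             sustain_threshold = 0.6,
                             min_peaks_sustained = 3,
                             steady_window = 0.1) {
  stopifnot(prominence_frac >= 0, amplitude_floor >= 0,
            sustain_threshold >= 0, min_peaks_sustained >= 2,
            steady_window > 0, steady_window <= 1)
  structure(
    list(prominence_frac = prominence_frac,
         amplitude_floor = amplitude_floor,
         sustain_threshold = sustain_threshold,
         min_peaks_sustained = min_peaks_sustained,
         steady_window = steady_window),
    class = "nfkb_settings"
  )
}

#' Detect prominent peaks and the troughs between them
#'
#' Finds interior local maxima (strictly above both neighbours), keeps
#' those passing the amplitude and prominence rules of
#' [feature_settings()], and records one trough per consecutive peak pair
#' (the minimum between the peaks), so peaks and troughs interleave by
#' construction.
#'
#' @param time Time grid (hours).
#' @param value Series values (same length, finite, >= 3 samples).
#' @param settings A [feature_settings()] list.
#' @return A tibble of class `nfkb_peaks` with columns `type`
#'   (`"peak"`/`"trough"`), `time_h`, `value`; empty when no peak passes
#'   the rules. Settings are attached as an attribute.
#' @export
detect_peaks <- function(time, value, settings = feature_settings()) {
  stopifnot(length(time) == length(value), length(value) >= 3,
            all(is.finite(value)))
  n <- length(value)
  i <- 2:(n - 1)
  cand <- i[value[i] > value[i - 1] & value[i] > value[i + 1]]
  gmax <- max(value)

  keep <- integer(0)
  if (length(cand) > 0) {
    # valleys flanking each candidate: minimum down to the previous/next
    # candidate (or to the series boundary)
    bounds <- c(1L, cand, n)
    vall <- vapply(seq_along(cand), function(j) {
      left <- min(value[bounds[j]:cand[j]])
      right <- min(value[cand[j]:bounds[j + 2]])
      max(left, right)
    }, numeric(1))
    prom <- value[cand] - vall
    keep <- cand[value[cand] >= settings$amplitude_floor &
                   prom >= settings$prominence_frac * gmax]
  }

  # interleaving: collapse runs that would give two peaks with no
  # intervening descent is already handled by candidate strictness; the
  # troughs are defined as the minimum between consecutive kept peaks
  rows <- list()
  if (length(keep) > 0) {
    rows[[1]] <- tibble::tibble(type = "peak", time_h = time[keep],
                                value = value[keep])
    if (length(keep) >= 2) {
      tt <- vapply(seq_len(length(keep) - 1), function(j) {
        seg <- keep[j]:keep[j + 1]
        seg[which.min(value[seg])]
      }, integer(1))
      rows[[2]] <- tibble::tibble(type = "trough", time_h = time[tt],
                                  value = value[tt])
    }
  }
  out <- if (length(rows) > 0) dplyr::arrange(dplyr::bind_rows(rows),
                                              .data$time_h)
         else tibble::tibble(type = character(0), time_h = numeric(0),
                             value = numeric(0))
  structure(out, settings = settings,
            class = c("nfkb_peaks", class(tibble::tibble())))
}

#' Extract the six dynamic features of a nuclear NF-kB profile
#'
#' The features are: the first maximum (amplitude of the first peak), the
#' first translocation time (its timing), the first period (time between
#' the first two peaks), and three ratios normalized by the first maximum:
#' the first minimum (the valley between the first two peaks), the second
#' maximum, and the steady state (mean over the final `steady_window`
#' fraction of the window). Features that do not exist for a trajectory
#' (e.g. the period of a single-peaked response) are `NA`, never zero.
#'
#' @param trajectory An `nfkb_trajectory` tibble (or any tibble with a
#'   `time_h` column).
#' @param species Column to analyse (default `"NFkBn"`).
#' @param settings A [feature_settings()] list.
#' @return A one-row tibble with the six features, `steady_state`,
#'   `n_peaks`, and logical `responder` (first maximum defined and above
#'   the amplitude floor).
#' @export
extract_features <- function(trajectory, species = "NFkBn",
                             settings = feature_settings()) {
  if (!species %in% names(trajectory)) {
    stop("unknown species '", species, "'", call. = FALSE)
  }
  tvec <- trajectory$time_h
  y <- trajectory[[species]]
  pk <- detect_peaks(tvec, y, settings)
  peaks <- pk[pk$type == "peak", ]
  troughs <- pk[pk$type == "trough", ]

  n_steady <- max(1L, ceiling(settings$steady_window * length(y)))
  steady <- mean(utils::tail(y, n_steady))

  first_max <- if (nrow(peaks) >= 1) peaks$value[1] else NA_real_
  first_time <- if (nrow(peaks) >= 1) peaks$time_h[1] else NA_real_
  second_max <- if (nrow(peaks) >= 2) peaks$value[2] else NA_real_
  period <- if (nrow(peaks) >= 2) peaks$time_h[2] - peaks$time_h[1]
            else NA_real_
  first_min <- if (nrow(peaks) >= 2 && nrow(troughs) >= 1)
    troughs$value[1] else NA_real_

  tibble::tibble(
    first_maximum = first_max,
    first_translocation_time = first_time,
    first_period = period,
    ratio_first_min_to_first_max = first_min / first_max,
    ratio_second_max_to_first_max = second_max / first_max,
    ratio_steady_state_to_first_max =
      if (is.na(first_max)) NA_real_ else steady / first_max,
    steady_state = steady,
    n_peaks = nrow(peaks),
    responder = !is.na(first_max) && first_max >= settings$amplitude_floor
  )
}

#' The four dynamic-pattern labels
#' @return Character vector of the labels in canonical order.
#' @export
pattern_levels <- function() {
  c("sustained_oscillation", "damped_oscillation", "single_peaked",
    "monotonic_increasing")
}

#' Classify a trajectory into one of four dynamic patterns
#'
#' Decision rule: no prominent peak -> `monotonic_increasing` (the
#' hyperbolic/over-damped class, which also absorbs flat non-responders);
#' exactly one peak -> `single_peaked`; two or more peaks ->
#' `sustained_oscillation` when the amplitude decays slowly
#' (second/first peak ratio >= `sustain_threshold` and at least
#' `min_peaks_sustained` peaks in the window), otherwise
#' `damped_oscillation`.
#'
#' @param features A one-row tibble from [extract_features()].
#' @param peaks The matching [detect_peaks()] result (optional; `n_peaks`
#'   from `features` is used when omitted).
#' @param settings A [feature_settings()] list.
#' @return One of [pattern_levels()].
#' @export
classify_pattern <- function(features, peaks = NULL,
                             settings = feature_settings()) {
  n_peaks <- if (!is.null(peaks)) sum(peaks$type == "peak")
             else features$n_peaks
  if (n_peaks == 0) return("monotonic_increasing")
  if (n_peaks == 1) return("single_peaked")
  ratio <- features$ratio_second_max_to_first_max
  if (!is.na(ratio) && ratio >= settings$sustain_threshold &&
        n_peaks >= settings$min_peaks_sustained) {
    "sustained_oscillation"
  } else {
    "damped_oscillation"
  }
}

#' Features and pattern labels for every replicate of an ensemble
#'
#' @param ensemble A [run_ensemble()] result.
#' @param species Species column (default `"NFkBn"`).
#' @param settings A [feature_settings()] list.
#' @return A tibble with `replicate`, the columns of [extract_features()],
#'   and `pattern`; skipped replicates are dropped.
#' @export
ensemble_features <- function(ensemble, species = "NFkBn",
                              settings = feature_settings()) {
  stopifnot(inherits(ensemble, "nfkb_ensemble"),
            "trajectory" %in% names(ensemble))
  idx <- which(ensemble$ok)
  rows <- lapply(idx, function(i) {
    tr <- ensemble$trajectory[[i]]
    f <- extract_features(tr, species, settings)
    f$pattern <- classify_pattern(f, settings = settings)
    f$replicate <- ensemble$replicate[i]
    f
  })
  dplyr::relocate(dplyr::bind_rows(rows), "replicate")
}

#' Histogram summaries of the dynamic-feature distributions
#'
#' @param features A tibble of per-replicate features
#'   ([ensemble_features()] output).
#' @param feature_names Features to summarize (default: the six dynamic
#'   features).
#' @param bins Number of uniform histogram bins over the observed range
#'   (default 50).
#' @return A tibble with one row per feature: `mean`, `mode` (midpoint of
#'   the modal bin), `sd`, `defined_fraction`, `n_defined`, and list
#'   columns `breaks` and `counts`. A feature with no defined values gets
#'   an empty summary row (all-`NA` statistics), not an error.
#' @export
feature_distributions <- function(features,
                                  feature_names = c(
                                    "first_maximum",
                                    "first_translocation_time",
                                    "first_period",
                                    "ratio_first_min_to_first_max",
                                    "ratio_second_max_to_first_max",
                                    "ratio_steady_state_to_first_max"),
                                  bins = 50) {
  stopifnot(bins >= 1)
  rows <- lapply(feature_names, function(f) {
    if (!f %in% names(features)) {
      stop("unknown feature '", f, "'", call. = FALSE)
    }
    x <- features[[f]]
    xd <- x[!is.na(x)]
    if (length(xd) == 0) {
      return(tibble::tibble(
        feature = f, mean = NA_real_, mode = NA_real_, sd = NA_real_,
        defined_fraction = 0, n_defined = 0L,
        breaks = list(numeric(0)), counts = list(integer(0))))
    }
    rng <- range(xd)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1e-12)
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    h <- graphics::hist(xd, breaks = brk, plot = FALSE,
                        include.lowest = TRUE)
    tibble::tibble(
      feature = f,
      mean = mean(xd),
      mode = h$mids[which.max(h$counts)],
      sd = stats::sd(xd),
      defined_fraction = length(xd) / length(x),
      n_defined = length(xd),
      breaks = list(h$breaks),
      counts = list(h$counts)
    )
  })
  dplyr::bind_rows(rows)
}

#' Fractions of the four dynamic patterns
#'
#' @param labels Character vector of pattern labels.
#' @return A tibble with one row per label of [pattern_levels()] and
#'   columns `pattern`, `n`, `fraction`; fractions sum to 1.
#' @export
pattern_distribution <- function(labels) {
  if (length(labels) == 0) stop("no labels", call. = FALSE)
  bad <- setdiff(unique(labels), pattern_levels())
  if (length(bad) > 0) {
    stop("unknown pattern label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(labels, levels = pattern_levels()))
  tibble::tibble(
    pattern = pattern_levels(),
    n = as.integer(counts),
    fraction = as.numeric(counts) / length(labels)
  )
}
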