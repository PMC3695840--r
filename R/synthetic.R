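#' Generate a synthetic test signal
#'
#' Deterministic waveforms (plus optional seeded Gaussian noise) used to
#' exercise the peak/feature/pattern analytics independently of the ODE
#' model.
#'
#' Families: `"constant"` (baseline + amplitude), `"saturating_exponential"`
#' (`baseline + amplitude * (1 - exp(-t / decay))`), `"damped_cosine"`
#' (`baseline + amplitude * exp(-t / decay) * (1 - cos(2 pi t / period)) / 2`,
#' peaks `period` apart with per-cycle amplitude decay
#' `exp(-period / decay)`), and `"sustained_sine"` (the same with no
#' decay).
#'
#' @param family Waveform family.
#' @param amplitude,period,decay,baseline Waveform parameters; times in
#'   hours, `decay` is the exponential time constant (`Inf` = no decay).
#' @param duration Signal length in hours.
#' @param sampling Sampling interval in hours (default 1/60).
#' @param noise Gaussian noise standard deviation (default 0).
#' @param seed Seed for the noise (required when `noise > 0`).
#' @return A tibble with `time_h` and `value`.
#' @examples
#' sig <- synthetic_signal("damped_cosine", period = 2, decay = 3,
#'                         duration = 10)
#' extract_features(dplyr::rename(sig, NFkBn = value))
#' @export
synthetic_signal <- function(family = c("constant",
                                        "saturating_exponential",
                                        "damped_cosine",
                                        "sustained_sine"),
                             amplitude = 1, period = 2, decay = Inf,
                             baseline = 0, duration = 10,
                             sampling = 1 / 60, noise = 0, seed = NULL) {
  family <- match.arg(family)
  stopifnot(duration > 0, sampling > 0, noise >= 0, period > 0, decay > 0)
  t <- seq(0, duration, by = sampling)
  value <- switch(
    family,
    constant = rep(baseline + amplitude, length(t)),
    saturating_exponential = baseline + amplitude * (1 - exp(-t / decay)),
    damped_cosine = baseline + amplitude * exp(-t / decay) *
      (1 - cos(2 * pi * t / period)) / 2,
    sustained_sine = baseline + amplitude *
      (1 - cos(2 * pi * t / period)) / 2
  )
  if (noise > 0) {
    if (is.null(seed)) stop("seed required when noise > 0", call. = FALSE)
    value <- value + with_local_seed(seed,
                                     stats::rnorm(length(t), 0, noise))
  }
  tibble::tibble(time_h = t, value = value)
}
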