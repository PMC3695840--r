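test_that("peak detection matches analytic extrema of smooth signals", {
  # constant signal: nothing to find
  flat <- synthetic_signal("constant", amplitude = 1, duration = 5)
  pk <- detect_peaks(flat$time_h, flat$value)
  expect_equal(nrow(pk), 0)

  # 1 + sin(t) on [0, 4 pi] (t in hours): peaks at pi/2 and 5 pi/2,
  # trough at 3 pi/2
  t <- seq(0, 4 * pi, by = 0.002)
  y <- 1 + sin(t)
  pk <- detect_peaks(t, y)
  peaks <- pk[pk$type == "peak", ]
  troughs <- pk[pk$type == "trough", ]
  expect_equal(peaks$time_h, c(pi / 2, 5 * pi / 2), tolerance = 1e-3)
  expect_equal(troughs$time_h, 3 * pi / 2, tolerance = 1e-3)
})

test_that("peak detection equals the exhaustive brute-force oracle", {
  set.seed(42)
  cases <- list(
    synthetic_signal("damped_cosine", period = 2, decay = 2, duration = 12,
                     noise = 0.01, seed = 5),
    synthetic_signal("sustained_sine", period = 1.5, duration = 12,
                     noise = 0.02, seed = 6),
    synthetic_signal("saturating_exponential", decay = 2, duration = 12),
    tibble::tibble(time_h = ref_trajectory()$time_h,
                   value = ref_trajectory()$NFkBn)
  )
  settings_list <- list(feature_settings(),
                        feature_settings(prominence_frac = 0.2),
                        feature_settings(amplitude_floor = 0.05))
  for (sig in cases) {
    for (s in settings_list) {
      pk <- detect_peaks(sig$time_h, sig$value, s)
      or <- oracle_peaks(sig$time_h, sig$value, s)
      expect_equal(pk$time_h[pk$type == "peak"], or$peak_t)
      expect_equal(pk$value[pk$type == "peak"], or$peak_v)
      expect_equal(pk$time_h[pk$type == "trough"], or$trough_t)
    }
  }
})

test_that("features of analytic signals match closed forms", {
  t <- seq(0, 4 * pi, by = 0.002)
  sin_traj <- tibble::tibble(time_h = t, NFkBn = 1 + sin(t))
  f <- extract_features(sin_traj)
  expect_equal(f$first_maximum, 2, tolerance = 1e-5)
  expect_equal(f$first_translocation_time, pi / 2, tolerance = 1e-3)
  expect_equal(f$first_period, 2 * pi, tolerance = 1e-3)
  expect_equal(f$ratio_first_min_to_first_max, 0, tolerance = 1e-5)
  expect_equal(f$ratio_second_max_to_first_max, 1, tolerance = 1e-5)

  sat <- synthetic_signal("saturating_exponential", decay = 1, duration = 15)
  sat_traj <- tibble::tibble(time_h = sat$time_h, NFkBn = sat$value)
  f2 <- extract_features(sat_traj)
  expect_true(is.na(f2$first_translocation_time))
  expect_true(is.na(f2$ratio_steady_state_to_first_max))
  expect_equal(f2$steady_state, 1, tolerance = 1e-3)

  expect_error(extract_features(sin_traj, species = "IKKa"), "unknown")
})

test_that("features agree with the peak list they derive from", {
  tr <- ref_trajectory()
  f <- extract_features(tr)
  pk <- detect_peaks(tr$time_h, tr$NFkBn)
  peaks <- pk[pk$type == "peak", ]
  expect_equal(f$first_maximum, peaks$value[1])
  expect_equal(f$first_translocation_time, peaks$time_h[1])
  expect_equal(f$first_period, diff(peaks$time_h[1:2]))
  expect_equal(f$n_peaks, nrow(peaks))
})

test_that("features are scale- and shift-equivariant", {
  tr <- ref_trajectory()
  f <- extract_features(tr)
  scaled <- tr
  scaled$NFkBn <- tr$NFkBn * 2
  fs <- extract_features(scaled)
  expect_equal(fs$first_maximum, 2 * f$first_maximum)
  for (r in c("ratio_first_min_to_first_max",
              "ratio_second_max_to_first_max",
              "ratio_steady_state_to_first_max")) {
    expect_equal(fs[[r]], f[[r]])
  }
  expect_equal(fs$first_translocation_time, f$first_translocation_time)
  expect_equal(fs$first_period, f$first_period)

  shifted <- tr
  shifted$time_h <- tr$time_h + 1.5
  ft <- extract_features(shifted)
  expect_equal(ft$first_translocation_time,
               f$first_translocation_time + 1.5)
  expect_equal(ft$first_period, f$first_period)
  expect_equal(ft$first_maximum, f$first_maximum)
})

test_that("the four-way classifier is total and matches the declared rule", {
  specs <- list(
    list(sig = synthetic_signal("sustained_sine", period = 2,
                                duration = 12),
         label = "sustained_oscillation"),
    list(sig = synthetic_signal("saturating_exponential", decay = 2,
                                duration = 12),
         label = "monotonic_increasing"),
    list(sig = synthetic_signal("constant", duration = 12),
         label = "monotonic_increasing"),
    # amplitude decay factor 0.3 per cycle: below the 0.6 sustain threshold
    list(sig = synthetic_signal("damped_cosine", period = 2,
                                decay = 2 / -log(0.3), duration = 12),
         label = "damped_oscillation"),
    # decay so strong only one prominent peak survives
    list(sig = synthetic_signal("damped_cosine", period = 2, decay = 0.3,
                                duration = 12),
         label = "single_peaked")
  )
  for (cs in specs) {
    traj <- tibble::tibble(time_h = cs$sig$time_h, NFkBn = cs$sig$value)
    f <- extract_features(traj)
    lab <- classify_pattern(f)
    expect_identical(lab, cs$label)
    expect_true(lab %in% pattern_levels())
  }
  # totality under varied settings on noisy signals
  set.seed(9)
  for (i in 1:10) {
    sig <- synthetic_signal("damped_cosine", period = runif(1, 1, 3),
                            decay = runif(1, 0.5, 10), duration = 12,
                            noise = 0.02, seed = i)
    traj <- tibble::tibble(time_h = sig$time_h, NFkBn = sig$value)
    s <- feature_settings(prominence_frac = runif(1, 0.01, 0.2),
                          sustain_threshold = runif(1, 0.3, 0.9))
    lab <- classify_pattern(extract_features(traj, settings = s),
                            settings = s)
    expect_length(intersect(lab, pattern_levels()), 1)
  }
})

test_that("feature distributions summarize defined values faithfully", {
  f <- acc_wt_features()
  d <- feature_distributions(f)
  expect_equal(nrow(d), 6)
  row <- d[d$feature == "first_translocation_time", ]
  x <- f$first_translocation_time
  expect_equal(row$mean, mean(x[!is.na(x)]))
  expect_equal(row$defined_fraction, mean(!is.na(x)))
  expect_equal(sum(row$counts[[1]]), sum(!is.na(x)))
  # point mass for a single replicate
  d1 <- feature_distributions(f[1, ])
  expect_equal(d1$mean[1], f$first_maximum[1])
  # an all-undefined feature yields a flagged empty summary, not an error
  fna <- f
  fna$first_period <- NA_real_
  dna <- feature_distributions(fna)
  expect_equal(dna$n_defined[dna$feature == "first_period"], 0L)
  expect_true(is.na(dna$mean[dna$feature == "first_period"]))
})

test_that("pattern fractions are a normalized four-way distribution", {
  labs <- c("damped_oscillation", "damped_oscillation", "single_peaked")
  pd <- pattern_distribution(labs)
  expect_equal(sum(pd$fraction), 1)
  expect_equal(pd$fraction[pd$pattern == "damped_oscillation"], 2 / 3)
  pd1 <- pattern_distribution(rep("single_peaked", 5))
  expect_equal(pd1$fraction[pd1$pattern == "single_peaked"], 1)
  expect_equal(sum(pd1$fraction), 1)
  expect_error(pattern_distribution(character(0)), "no labels")
  expect_error(pattern_distribution("wiggly"), "unknown pattern")
})

test_that("larger dosage gives earlier, narrower translocation times", {
  f_hi <- acc_wt_features()
  f_lo <- acc_small_features()
  t_hi <- f_hi$first_translocation_time
  t_lo <- f_lo$first_translocation_time
  expect_gt(sum(!is.na(t_lo)), 2)
  expect_lt(mean(t_hi, na.rm = TRUE), mean(t_lo, na.rm = TRUE))
  expect_lt(stats::sd(t_hi, na.rm = TRUE), stats::sd(t_lo, na.rm = TRUE))
})
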