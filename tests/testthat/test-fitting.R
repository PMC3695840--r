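# small pilot ensemble shared by the fitting tests
fit_pilot <- function() cached("fit_pilot", {
  ens <- lhs_sample(ref_params(), n = 100, chi = 0.3, seed = 7)
  run_ensemble(ens, nfkb_protocol(TR = 1, t_stimulate = 10))
})
fit_pilot_features <- function() cached("fit_pilot_f",
                                        ensemble_features(fit_pilot()))

test_that("correlation ranking is deterministic and handles degeneracies", {
  ens <- fit_pilot()
  fs <- fit_pilot_features()
  c1 <- feature_parameter_correlation(ens, fs)
  c2 <- feature_parameter_correlation(ens, fs)
  expect_identical(c1, c2)
  expect_true(all(abs(c1$correlation) <= 1, na.rm = TRUE))

  # a parameter with a zero-width interval has no rank correlation
  ens0 <- lhs_sample(ref_params(), n = 100, chi = 0.3, seed = 7,
                     sampled_symbols = c("K1", "Aa", "Ub"))
  attr(ens0, "config")$sampled_symbols <- c("K1", "Aa", "Ub")
  ens0$trajectory <- ens$trajectory
  ens0$ok <- ens$ok
  cc <- feature_parameter_correlation(ens0, fs,
                                      feature_names = "first_maximum")
  expect_true(is.na(cc$correlation[cc$symbol == "Ub"]))

  # a duplicated parameter column gets an identical correlation row
  dup <- ens
  dup$Aa <- dup$K1
  cd <- feature_parameter_correlation(dup, fs,
                                      feature_names = "first_maximum")
  expect_equal(unname(cd$correlation[cd$symbol == "Aa"]),
               unname(cd$correlation[cd$symbol == "K1"]))

  # features defined in too few replicates are excluded with a warning
  few <- fs
  few$first_period[-(1:5)] <- NA
  expect_warning(
    ex <- feature_parameter_correlation(ens, few,
                                        feature_names = "first_period"),
    "excluded")
  expect_equal(nrow(ex), 0)
})

test_that("first-peak timing is controlled by the IKK supply module", {
  corr <- feature_parameter_correlation(fit_pilot(), fit_pilot_features())
  top <- top_parameters(corr, 2)
  timing_top <- top$symbol[top$feature == "first_translocation_time"]
  ikk_module <- c("K1", "K2", "K3", "Kprod", "Kdeg")
  expect_true(all(timing_top %in% ikk_module))

  # brute-force one-at-a-time oracle: perturbing the top-ranked constant
  # shifts the first-peak time in the direction of its correlation sign
  p <- ref_params()
  sym <- timing_top[1]
  sgn <- unname(sign(
    corr$correlation[corr$feature == "first_translocation_time" &
                       corr$symbol == sym]))
  t_of <- function(q) {
    tr <- suppressWarnings(
      simulate_response(q, nfkb_protocol(TR = 1, t_stimulate = 6)))
    extract_features(tr)$first_translocation_time
  }
  up <- p; up[[sym]] <- up[[sym]] * 1.5
  dn <- p; dn[[sym]] <- dn[[sym]] / 1.5
  expect_equal(sign(t_of(up) - t_of(dn)), sgn)
})

test_that("targets equal to the current ensemble-average are a fixed point", {
  p <- ref_params()
  cfg <- fit_config(n_fit = 25, pilot_n = 25, seed = 3,
                    pairs = tibble::tibble(feature = "first_maximum",
                                           symbol = "Kprod",
                                           correlation = 1))
  feats <- nfkbse:::se_average_features(p, cfg$n_fit, cfg$chi, cfg)
  tg <- fit_targets(c(first_maximum = feats$first_maximum))
  fit <- suppressWarnings(fit_to_targets(tg, p, cfg))
  expect_true(fit$converged)
  expect_equal(fit$iterations, 0L)
  expect_equal(nrow(fit$history), 0L)
  expect_identical(unclass(fit$params), unclass(p))
  expect_equal(unname(fit$deviations$deviation), 0)
})

test_that("fits are deterministic and keep monotone bookkeeping", {
  p <- ref_params()
  init <- p
  init[["Kprod"]] <- init[["Kprod"]] * 1.4
  cfg <- fit_config(n_fit = 25, pilot_n = 25, seed = 3, max_iterations = 3,
                    pairs = tibble::tibble(feature = "first_maximum",
                                           symbol = "Kprod",
                                           correlation = 1))
  feats <- nfkbse:::se_average_features(p, cfg$n_fit, cfg$chi, cfg)
  tg <- fit_targets(c(first_maximum = feats$first_maximum))
  f1 <- suppressWarnings(fit_to_targets(tg, init, cfg))
  f2 <- suppressWarnings(fit_to_targets(tg, init, cfg))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  acc <- f1$history[f1$history$accepted, ]
  expect_true(all(acc$deviation_after <= acc$deviation_before))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_identical(nrow(glance(f1)), 1L)
})

test_that("infeasible targets trigger the chi schedule and best-so-far", {
  p <- ref_params()
  # a deliberately mis-assigned step direction: every proposal moves the
  # feature away from the (unreachable) target and is rolled back, which
  # drives the step-size halving and then the chi schedule
  cfg <- fit_config(n_fit = 15, pilot_n = 15, seed = 3, max_iterations = 6,
                    eta = 0.1, eta_min = 0.06, chi_step = 0.1,
                    pairs = tibble::tibble(feature = "first_maximum",
                                           symbol = "Kprod",
                                           correlation = -1))
  tg <- fit_targets(c(first_maximum = 10))
  fit <- suppressWarnings(fit_to_targets(tg, p, cfg))
  expect_false(fit$converged)
  expect_s3_class(fit$params, "nfkb_params")
  chis <- fit$history$chi
  expect_true(all(diff(chis) <= 0))       # non-increasing schedule
  expect_lt(min(chis), cfg$chi)           # schedule actually advanced
})

test_that("target validation rejects degenerate inputs", {
  expect_error(fit_targets(c(first_maximum = 0)), "nonzero")
  expect_error(fit_targets(numeric(0)), "length")
  expect_error(fit_targets(c(first_maximum = 1), tolerance = 0), "tolerance")
})
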