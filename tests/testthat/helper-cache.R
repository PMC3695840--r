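# Shared fixtures, computed lazily and cached for the whole run.
# Ensembles are scaled to 200 replicates (analysis-grade runs use 1000);
# unit tests use much smaller ensembles built inline.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- suppressMessages(suppressWarnings(force(expr)))
  }
  .fixture_cache[[key]]
}

FIXTURE_SEED <- 1234L
ACC_N <- 200L

ref_params <- function() cached("params", nfkb_parameters("fitted"))

# wild type, TR = 1, chi = 0.3
acc_wt_ensemble <- function() cached("acc_wt", {
  ens <- lhs_sample(ref_params(), n = ACC_N, chi = 0.3, seed = FIXTURE_SEED)
  run_ensemble(ens, nfkb_protocol(TR = 1, t_stimulate = 10))
})

# IkBb/IkBe double knockout, TR = 1, chi = 0.3
acc_bke_ensemble <- function() cached("acc_bke", {
  ens <- lhs_sample(ref_params(), n = ACC_N, chi = 0.3, seed = FIXTURE_SEED)
  run_ensemble(ens, nfkb_protocol(TR = 1, t_stimulate = 10),
               genotype = c("IkBb", "IkBe"))
})

# wild type, small dosage TR = 0.01
acc_small_ensemble <- function() cached("acc_small", {
  ens <- lhs_sample(ref_params(), n = ACC_N, chi = 0.3, seed = FIXTURE_SEED)
  run_ensemble(ens, nfkb_protocol(TR = 0.01, t_stimulate = 10))
})

acc_wt_features <- function() cached("acc_wt_f",
                                     ensemble_features(acc_wt_ensemble()))
acc_bke_features <- function() cached("acc_bke_f",
                                      ensemble_features(acc_bke_ensemble()))
acc_small_features <- function() cached("acc_small_f",
                                        ensemble_features(acc_small_ensemble()))

# one reference wild-type trajectory (fitted parameters, TR = 1)
ref_trajectory <- function() cached("ref_traj", {
  simulate_response(ref_params(), nfkb_protocol(TR = 1, t_stimulate = 10))
})

# small ensemble for plumbing tests
small_wt_ensemble <- function() cached("small_wt", {
  ens <- lhs_sample(ref_params(), n = 20, chi = 0.3, seed = FIXTURE_SEED)
  run_ensemble(ens, nfkb_protocol(TR = 1, t_stimulate = 10))
})

# brute-force peak/trough oracle: tests every interior grid point against
# both neighbours, applies the same prominence/amplitude rules, then takes
# the minimum between consecutive kept peaks as the troughs
oracle_peaks <- function(time, value, settings = feature_settings()) {
  n <- length(value)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (value[i] > value[i - 1] && value[i] > value[i + 1]) {
      cand <- c(cand, i)
    }
  }
  gmax <- max(value)
  keep <- integer(0)
  for (j in seq_along(cand)) {
    lo <- if (j == 1) 1L else cand[j - 1]
    hi <- if (j == length(cand)) n else cand[j + 1]
    vall <- max(min(value[lo:cand[j]]), min(value[cand[j]:hi]))
    if (value[cand[j]] >= settings$amplitude_floor &&
          value[cand[j]] - vall >= settings$prominence_frac * gmax) {
      keep <- c(keep, cand[j])
    }
  }
  troughs <- integer(0)
  if (length(keep) >= 2) {
    for (j in seq_len(length(keep) - 1)) {
      seg <- keep[j]:keep[j + 1]
      troughs <- c(troughs, seg[which.min(value[seg])])
    }
  }
  list(peak_t = time[keep], peak_v = value[keep],
       trough_t = time[troughs], trough_v = value[troughs])
}

# toy single-species exponential-decay model for the integrator
decay_model <- function(rate = 1) {
  list(k = rate, sub1 = 1L, sub2 = 0L, Si = 1L, Sj = 1L, Sx = -1,
       species = "y")
}
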