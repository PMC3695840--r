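#' Rank-correlate sampled parameters with dynamic features
#'
#' Computes the Spearman rank correlation between every sampled rate
#' constant and every dynamic feature across the replicates of a simulated
#' ensemble, and ranks, per feature, the parameters by absolute
#' correlation. Parameters held fixed across replicates (zero-width
#' sampling interval) have no rank correlation and are reported as `NA`.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param features Matching [ensemble_features()] tibble.
#' @param feature_names Features to correlate (default: the six dynamic
#'   features).
#' @param min_defined Features defined in fewer replicates are excluded
#'   with a warning (default 10).
#' @return A tibble with columns `feature`, `symbol`, `correlation`,
#'   `abs_correlation`, `rank` (1 = strongest within the feature).
#' @export
feature_parameter_correlation <- function(ensemble, features,
                                          feature_names = c(
                                            "first_maximum",
                                            "first_translocation_time",
                                            "first_period",
                                            "ratio_first_min_to_first_max",
                                            "ratio_second_max_to_first_max",
                                            "ratio_steady_state_to_first_max"),
                                          min_defined = 10) {
  stopifnot(inherits(ensemble, "nfkb_ensemble"))
  cfg <- attr(ensemble, "config")
  syms <- cfg$sampled_symbols
  joined <- dplyr::inner_join(
    ensemble[, c("replicate", syms)], features,
    by = "replicate"
  )
  rows <- list()
  for (f in feature_names) {
    x <- joined[[f]]
    ok <- !is.na(x)
    if (sum(ok) < min_defined) {
      warning("feature '", f, "' defined in only ", sum(ok),
              " replicates; excluded", call. = FALSE)
      next
    }
    cors <- vapply(syms, function(s) {
      p <- joined[[s]][ok]
      if (stats::sd(p) == 0 || stats::sd(x[ok]) == 0) return(NA_real_)
      stats::cor(p, x[ok], method = "spearman")
    }, numeric(1))
    tb <- tibble::tibble(feature = f, symbol = syms, correlation = cors,
                         abs_correlation = abs(cors))
    tb <- dplyr::arrange(tb, dplyr::desc(
      dplyr::coalesce(.data$abs_correlation, -Inf)))
    tb$rank <- seq_len(nrow(tb))
    rows[[f]] <- tb
  }
  dplyr::bind_rows(rows)
}

#' Top-k parameters per feature from a correlation table
#'
#' @param correlations Output of [feature_parameter_correlation()].
#' @param k Parameters per feature (default 2).
#' @return Tibble `feature`, `symbol`, `correlation`, `rank`.
#' @export
top_parameters <- function(correlations, k = 2) {
  dplyr::filter(correlations, .data$rank <= k, !is.na(.data$correlation))[,
    c("feature", "symbol", "correlation", "rank")]
}

#' Target features for ensemble-average fitting
#'
#' @param values Named numeric vector of target values; names are dynamic
#'   features as in [extract_features()].
#' @param tolerance Relative tolerance per feature, recycled (default
#'   0.15).
#' @param weights Per-feature weights, recycled (default 1).
#' @return A tibble of class `nfkb_targets` with columns `feature`,
#'   `target`, `tolerance`, `weight`.
#' @export
fit_targets <- function(values, tolerance = 0.15, weights = 1) {
  stopifnot(is.numeric(values), length(values) >= 1,
            !is.null(names(values)), all(tolerance > 0))
  tb <- tibble::tibble(
    feature = names(values),
    target = unname(values),
    tolerance = rep_len(tolerance, length(values)),
    weight = rep_len(weights, length(values))
  )
  if (any(!is.finite(tb$target)) || any(tb$target == 0)) {
    stop("targets must be finite and nonzero (relative deviations)",
         call. = FALSE)
  }
  structure(tb, class = c("nfkb_targets", class(tb)))
}

#' Configuration of the heuristic ensemble fit
#'
#' @param n_fit Replicates per fitting iteration (default 200).
#' @param pilot_n Replicates of the pilot ensemble used to assign the two
#'   most-correlated parameters to each feature (default 100).
#' @param chi Initial heterogeneity factor (default 0.3).
#' @param chi_step Step-like decrement of `chi` when the search stalls
#'   (default 0.05).
#' @param eta Multiplicative step size: an adjusted parameter is scaled by
#'   `(1 + eta)` or `1 / (1 + eta)` (default 0.2); halved on rejection.
#' @param eta_min When `eta` falls below this, the `chi` schedule advances
#'   and `eta` resets (default 0.02).
#' @param max_iterations Iteration cap (default 20).
#' @param seed Seed shared by every ensemble generation inside the fit, so
#'   deviation changes between iterations come from the parameters alone.
#' @param protocol Stimulation protocol for the fit ensembles.
#' @param genotype Knockout genes.
#' @param species Species whose SE average is fitted.
#' @param settings Feature-extraction settings.
#' @param pairs Optional override of the feature-to-parameter assignment:
#'   a tibble with columns `feature`, `symbol`, `correlation` (sign used
#'   for the step direction). When `NULL`, pairs are computed from the
#'   pilot ensemble.
#' @return A list of class `nfkb_fit_config`.
#' @export
fit_config <- function(n_fit = 200, pilot_n = 100, chi = 0.3,
                       chi_step = 0.05, eta = 0.2, eta_min = 0.02,
                       max_iterations = 20, seed = 1,
                       protocol = nfkb_protocol(),
                       genotype = character(0), species = "NFkBn",
                       settings = feature_settings(), pairs = NULL) {
  stopifnot(n_fit >= 1, pilot_n >= 1, chi >= 0, chi < 1, chi_step > 0,
            eta > 0, eta_min > 0, max_iterations >= 1)
  structure(
    list(n_fit = n_fit, pilot_n = pilot_n, chi = chi, chi_step = chi_step,
         eta = eta, eta_min = eta_min, max_iterations = max_iterations,
         seed = seed, protocol = protocol, genotype = genotype,
         species = species, settings = settings, pairs = pairs),
    class = "nfkb_fit_config"
  )
}

# SE-average features of an ensemble around `params`
se_average_features <- function(params, n, chi, config) {
  ens <- lhs_sample(params, n = n, chi = chi, seed = config$seed)
  ens <- run_ensemble(ens, config$protocol, config$genotype)
  avg <- ensemble_average(ens, config$species)
  tr <- tibble::tibble(time_h = avg$time_h)
  tr[[config$species]] <- avg$value
  extract_features(tr, config$species, config$settings)
}

# relative deviations of the SE-average features from the targets;
# undefined features get a large finite penalty so the search is driven
# toward restoring them
target_deviations <- function(feats, targets, penalty = 10) {
  vals <- vapply(targets$feature, function(f) {
    if (!f %in% names(feats)) {
      stop("unknown target feature '", f, "'", call. = FALSE)
    }
    feats[[f]]
  }, numeric(1))
  dev <- abs(vals - targets$target) / abs(targets$target)
  dev[is.na(dev)] <- penalty
  if (any(!is.finite(dev))) {
    stop("non-finite deviation for feature(s): ",
         paste(targets$feature[!is.finite(dev)], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(feature = targets$feature, value = vals, deviation = dev,
                 weighted = dev * targets$weight,
                 within = dev <= targets$tolerance)
}

#' Fit the ensemble-average features to target values
#'
#' Heuristic coordinate search: generate an ensemble around the current
#' parameters, extract the dynamic features of its equal-weight average,
#' find the target feature with the largest weighted relative deviation,
#' and nudge the two parameters most correlated with that feature by a
#' multiplicative step whose direction comes from the correlation sign and
#' the sign of the required change. Rejected steps (worst deviation did
#' not improve) are rolled back with the step size halved; when the step
#' size underflows, the heterogeneity factor `chi` is decreased step-like
#' and the search continues. The fit stops when every deviation is within
#' tolerance, the iteration cap is reached, or the `chi` schedule is
#' exhausted.
#'
#' @param targets A [fit_targets()] tibble.
#' @param init Initial `nfkb_params`.
#' @param config A [fit_config()] list.
#' @return An object of class `nfkb_fit`: list with `params` (best
#'   parameters), `deviations` (final per-feature table), `history`
#'   (per-iteration log), `pairs`, `converged`, `iterations`, `chi_final`,
#'   plus the inputs. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_to_targets <- function(targets, init, config = fit_config()) {
  stopifnot(inherits(targets, "nfkb_targets"),
            inherits(init, "nfkb_params"),
            inherits(config, "nfkb_fit_config"))

  pairs <- config$pairs
  if (is.null(pairs)) {
    pilot <- lhs_sample(init, n = config$pilot_n, chi = max(config$chi, 0.1),
                        seed = config$seed)
    pilot <- run_ensemble(pilot, config$protocol, config$genotype)
    pfeat <- ensemble_features(pilot, config$species, config$settings)
    corr <- feature_parameter_correlation(pilot, pfeat,
                                          feature_names = targets$feature)
    pairs <- top_parameters(corr, k = 2)
  }

  chi <- config$chi
  eta <- config$eta
  params <- init
  dev <- target_deviations(
    se_average_features(params, config$n_fit, chi, config), targets)
  best <- list(params = params, dev = dev, chi = chi)
  history <- list()
  iter <- 0L
  converged <- all(dev$within)

  while (!converged && iter < config$max_iterations && chi >= 0) {
    iter <- iter + 1L
    worst <- dev$feature[which.max(dev$weighted)]
    worst_dev <- dev$deviation[dev$feature == worst]
    pp <- pairs[pairs$feature == worst, ]
    if (nrow(pp) == 0) {
      warning("no parameters assigned to feature '", worst,
              "'; stopping", call. = FALSE)
      break
    }
    need <- sign(targets$target[targets$feature == worst] -
                   dev$value[dev$feature == worst])
    if (is.na(need) || need == 0) need <- 1
    cand <- params
    for (j in seq_len(nrow(pp))) {
      dir <- need * sign(pp$correlation[j])
      fac <- if (dir >= 0) (1 + eta) else 1 / (1 + eta)
      cand[[pp$symbol[j]]] <- max(cand[[pp$symbol[j]]] * fac,
                                  .Machine$double.xmin)
    }
    cand_dev <- target_deviations(
      se_average_features(cand, config$n_fit, chi, config), targets)
    cand_worst <- cand_dev$deviation[cand_dev$feature == worst]
    accepted <- cand_worst <= worst_dev
    history[[iter]] <- tibble::tibble(
      iteration = iter, chi = chi, eta = eta, worst_feature = worst,
      deviation_before = worst_dev, deviation_after = cand_worst,
      adjusted = paste(pp$symbol, collapse = ","), accepted = accepted
    )
    if (accepted) {
      params <- cand
      dev <- cand_dev
      if (max(dev$weighted) < max(best$dev$weighted)) {
        best <- list(params = params, dev = dev, chi = chi)
      }
    } else {
      eta <- eta / 2
      if (eta < config$eta_min) {
        chi <- chi - config$chi_step   # step-like decrease of heterogeneity
        eta <- config$eta
        if (chi >= 0) {
          dev <- target_deviations(
            se_average_features(params, config$n_fit, chi, config), targets)
        }
      }
    }
    converged <- all(dev$within)
  }

  if (converged) best <- list(params = params, dev = dev, chi = chi)
  structure(
    list(params = best$params, deviations = best$dev,
         history = dplyr::bind_rows(history), pairs = pairs,
         converged = converged, iterations = iter,
         chi_final = best$chi, targets = targets, init = init,
         config = config),
    class = "nfkb_fit"
  )
}

#' @export
print.nfkb_fit <- function(x, ...) {
  cat("<nfkb_fit> ", if (x$converged) "converged" else "not converged",
      " after ", x$iterations, " iteration(s), chi = ", x$chi_final,
      "\n", sep = "")
  print(x$deviations)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-feature summary of a fit
#'
#' @param x An `nfkb_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per target feature: `feature`, `target`,
#'   `value`, `deviation`, `tolerance`, `within`.
#' @export
tidy.nfkb_fit <- function(x, ...) {
  dplyr::inner_join(
    x$deviations[, c("feature", "value", "deviation", "within")],
    x$targets[, c("feature", "target", "tolerance")],
    by = "feature"
  )[, c("feature", "target", "value", "deviation", "tolerance", "within")]
}

#' One-row summary of a fit
#'
#' @param x An `nfkb_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `converged`, `iterations`, `chi_final`,
#'   `worst_deviation`, `n_fit`.
#' @export
glance.nfkb_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    iterations = x$iterations,
    chi_final = x$chi_final,
    worst_deviation = max(x$deviations$deviation),
    n_fit = x$config$n_fit
  )
}
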