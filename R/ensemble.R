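# run code under a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic 31-adic string hash, kept below 2^31 - 1
symbol_hash <- function(sym) {
  h <- 0
  for (c in utf8ToInt(sym)) h <- (h * 31 + c) %% 2147483629
  h
}

symbol_seed <- function(master_seed, sym) {
  as.integer((as.numeric(master_seed) %% 2147483629 * 7919 +
                symbol_hash(sym)) %% 2147483629)
}

#' Default set of randomized symbols
#'
#' All kinetic rate constants with a nonzero reference value. The
#' structural constants `Kv` and `NFkB_total` are fixed, and zero-valued
#' rates (constitutive A20 transcription, knocked-out synthesis rates)
#' have a zero-width sampling interval and stay exactly zero.
#'
#' @param reference An `nfkb_params` vector.
#' @return Character vector of symbols.
#' @export
default_sampled_symbols <- function(reference) {
  syms <- setdiff(names(reference), c("Kv", "NFkB_total"))
  syms[reference[syms] > 0]
}

#' Generate a statistical ensemble of parameter sets by Latin hypercube sampling
#'
#' Each randomized rate constant with reference value `x0` is sampled from
#' the uniform interval `(x0 * (1 - chi), x0 * (1 + chi))`, where `chi` is
#' the heterogeneity factor. Sampling is Latin hypercube: the interval is
#' split into `n` equal-probability strata, one value is drawn uniformly
#' within each stratum, and the `n` values are assigned to replicates by an
#' independent random permutation per symbol. Each symbol draws from its
#' own seed stream (derived from `seed` and the symbol name), so adding a
#' symbol to `sampled_symbols` does not reshuffle the others.
#'
#' @param reference An `nfkb_params` vector of reference (midpoint) values.
#' @param n Number of replicates (default 1000).
#' @param chi Heterogeneity factor in `[0, 1)` (default 0.3).
#' @param seed Master RNG seed.
#' @param sampled_symbols Symbols to randomize; default
#'   [default_sampled_symbols()].
#' @return A tibble of class `nfkb_ensemble`: column `replicate` plus one
#'   column per parameter symbol; configuration kept in attributes.
#' @examples
#' ens <- lhs_sample(nfkb_parameters(), n = 10, chi = 0.3, seed = 1)
#' range(ens$K1) # within 0.003273 * c(0.7, 1.3)
#' @export
lhs_sample <- function(reference, n = 1000, chi = 0.3, seed = 1,
                       sampled_symbols = NULL) {
  stopifnot(inherits(reference, "nfkb_params"))
  if (!(is.numeric(n) && length(n) == 1 && n >= 1)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (!(is.numeric(chi) && length(chi) == 1 && chi >= 0 && chi < 1)) {
    stop("chi must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(sampled_symbols)) {
    sampled_symbols <- default_sampled_symbols(reference)
  }
  unknown <- setdiff(sampled_symbols, names(reference))
  if (length(unknown) > 0) {
    stop("unknown sampled symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  cols <- lapply(names(reference), function(sym) {
    x0 <- reference[[sym]]
    if (!(sym %in% sampled_symbols) || chi == 0 || x0 == 0) {
      return(rep(x0, n))
    }
    with_local_seed(symbol_seed(seed, sym), {
      perm <- sample.int(n)
      u <- stats::runif(n)
      q <- (perm - u) / n                  # one value per stratum
      x0 * (1 - chi) + (2 * chi * x0) * q
    })
  })
  names(cols) <- names(reference)
  out <- tibble::as_tibble(cols)
  out <- tibble::add_column(out, replicate = seq_len(n), .before = 1)
  structure(out,
            config = list(n = n, chi = chi, seed = seed,
                          sampled_symbols = sampled_symbols,
                          reference = reference),
            class = c("nfkb_ensemble", class(out)))
}

#' Parameter set of one ensemble replicate
#'
#' @param ensemble An [lhs_sample()] ensemble.
#' @param i Replicate index.
#' @return An `nfkb_params` vector.
#' @export
ensemble_params <- function(ensemble, i) {
  syms <- nfkb_symbols()
  p <- as.numeric(ensemble[i, syms])
  names(p) <- syms
  structure(p, class = c("nfkb_params", "numeric"))
}

#' Simulate every replicate of an ensemble
#'
#' Applies the genotype knockout to each replicate's parameters and runs
#' [simulate_response()] independently for each; replicates share the
#' protocol (hence one common output time grid) and never interact, so the
#' execution order cannot affect the result.
#'
#' @param ensemble An [lhs_sample()] ensemble.
#' @param protocol An [nfkb_protocol()].
#' @param genotype Knockout genes, as in [apply_knockout()].
#' @param on_error `"abort"` (default) propagates an integration failure
#'   with the replicate index; `"skip"` records the failure and continues.
#' @return The ensemble tibble with list-column `trajectory`, logical
#'   column `ok`, and character column `fail_reason`, plus `protocol` and
#'   `genotype` attributes.
#' @export
run_ensemble <- function(ensemble, protocol = nfkb_protocol(),
                         genotype = character(0),
                         on_error = c("abort", "skip")) {
  stopifnot(inherits(ensemble, "nfkb_ensemble"),
            inherits(protocol, "nfkb_protocol"))
  on_error <- match.arg(on_error)
  n <- nrow(ensemble)
  trajs <- vector("list", n)
  ok <- rep(TRUE, n)
  fail <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      p <- apply_knockout(ensemble_params(ensemble, i), genotype)
      validate_params(p)
      simulate_response(p, protocol)
    }, error = identity)
    if (inherits(res, "error")) {
      if (on_error == "abort") {
        stop("replicate ", i, " failed: ", conditionMessage(res),
             call. = FALSE)
      }
      ok[i] <- FALSE
      fail[i] <- conditionMessage(res)
    } else {
      trajs[[i]] <- res
    }
  }
  out <- ensemble
  out$trajectory <- trajs
  out$ok <- ok
  out$fail_reason <- fail
  attr(out, "protocol") <- protocol
  attr(out, "genotype") <- genotype
  out
}

#' Equal-weight ensemble average of one species
#'
#' Pointwise arithmetic mean over replicates (skipped replicates are
#' excluded with a message). All trajectories must share one time grid.
#'
#' @param ensemble A [run_ensemble()] result.
#' @param species Species name (default `"NFkBn"`, nuclear NF-kB).
#' @return A tibble with `time_h` and `value` (the SE average).
#' @export
ensemble_average <- function(ensemble, species = "NFkBn") {
  stopifnot(inherits(ensemble, "nfkb_ensemble"),
            "trajectory" %in% names(ensemble))
  trajs <- ensemble$trajectory[ensemble$ok]
  if (length(trajs) == 0) stop("no successful replicates", call. = FALSE)
  nskip <- sum(!ensemble$ok)
  if (nskip > 0) {
    message(nskip, " skipped replicate(s) excluded from the average")
  }
  if (!species %in% names(trajs[[1]])) {
    stop("unknown species '", species, "'", call. = FALSE)
  }
  t0 <- trajs[[1]]$time_h
  for (tr in trajs) {
    if (length(tr$time_h) != length(t0) || any(tr$time_h != t0)) {
      stop("trajectories do not share one time grid", call. = FALSE)
    }
  }
  vals <- vapply(trajs, function(tr) tr[[species]], numeric(length(t0)))
  tibble::tibble(time_h = t0, value = rowMeans(vals))
}
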