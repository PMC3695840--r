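#' Species of the NF-kB network model
#'
#' The model tracks 28 species: the three IKK forms, free cytoplasmic and
#' nuclear NF-kB, A20 protein and mRNA, and for each IkB isoform
#' (a = alpha, b = beta, e = epsilon) the free cytoplasmic and nuclear
#' protein, the mRNA, the cytoplasmic and nuclear IkB:NF-kB complexes, and
#' the IKK-bound complexes.
#'
#' @return A tibble with columns `species`, `compartment` (`"cyt"` or
#'   `"nuc"`), and `nfkb_units` (number of NF-kB molecules the species
#'   carries, used by the conservation check).
#' @export
nfkb_species <- function() {
  iso <- c("a", "b", "e")
  sp <- list(
    list("IKKn", "cyt", 0), list("IKKa", "cyt", 0), list("IKKi", "cyt", 0),
    list("NFkB", "cyt", 1), list("NFkBn", "nuc", 1),
    list("A20", "cyt", 0), list("A20t", "cyt", 0)
  )
  for (i in iso) {
    sp <- c(sp, list(
      list(paste0("IkB", i), "cyt", 0),
      list(paste0("IkB", i, "n"), "nuc", 0),
      list(paste0("IkB", i, "t"), "cyt", 0),
      list(paste0("IkB", i, "_NFkB"), "cyt", 1),
      list(paste0("IkB", i, "n_NFkBn"), "nuc", 1),
      list(paste0("IKKa_IkB", i), "cyt", 0),
      list(paste0("IKKa_IkB", i, "_NFkB"), "cyt", 1)
    ))
  }
  tibble::tibble(
    species = vapply(sp, function(x) x[[1]], character(1)),
    compartment = vapply(sp, function(x) x[[2]], character(1)),
    nfkb_units = vapply(sp, function(x) x[[3]], numeric(1))
  )
}

# One flux per entry; `row` is the reaction string of the packaged table row
# the flux comes from (several fluxes can share a row when the table lists
# multiple substrates, e.g. the shared Kdeg and W* degradation rows).
# `subs` are the mass-action substrates (0-2); catalysts that appear on both
# sides are omitted from `stoich`. `home` overrides the compartment whose
# concentration units the flux is written in (defaults to the substrates'
# compartment); induced-transcription fluxes are written directly in
# cytoplasmic mRNA units.
rxn <- function(row, sym, subs, stoich, home = NULL, tr = FALSE) {
  list(row = row, sym = sym, subs = subs, stoich = stoich, home = home,
       tr = tr)
}

nfkb_reaction_list <- function() {
  r <- list(
    rxn("NFkBn -> NFkBn + A20t", "C1", "NFkBn", c(A20t = 1), home = "cyt"),
    rxn("0 -> A20t", "C2", character(0), c(A20t = 1)),
    rxn("A20t -> 0", "C3", "A20t", c(A20t = -1)),
    rxn("A20t -> A20t + A20", "C4", "A20t", c(A20 = 1)),
    rxn("A20 -> 0", "C5", "A20", c(A20 = -1)),
    rxn("NFkB -> NFkBn", "I1", "NFkB", c(NFkB = -1, NFkBn = 1)),
    rxn("NFkBn -> NFkB", "K01", "NFkBn", c(NFkBn = -1, NFkB = 1),
        home = "cyt"),
    rxn("IKKn -> IKKa", "K1", "IKKn", c(IKKn = -1, IKKa = 1), tr = TRUE),
    rxn("A20 + IKKa -> A20 + IKKi", "K2", c("A20", "IKKa"),
        c(IKKa = -1, IKKi = 1)),
    rxn("IKKa -> IKKi", "K3", "IKKa", c(IKKa = -1, IKKi = 1)),
    rxn("0 -> IKKn", "Kprod", character(0), c(IKKn = 1)),
    rxn("IKKn, IKKa, or IKKi -> 0", "Kdeg", "IKKn", c(IKKn = -1)),
    rxn("IKKn, IKKa, or IKKi -> 0", "Kdeg", "IKKa", c(IKKa = -1)),
    rxn("IKKn, IKKa, or IKKi -> 0", "Kdeg", "IKKi", c(IKKi = -1))
  )
  for (i in c("a", "b", "e")) {
    IkB <- paste0("IkB", i)
    IkBn <- paste0("IkB", i, "n")
    IkBt <- paste0("IkB", i, "t")
    IkB_N <- paste0("IkB", i, "_NFkB")
    IkBn_Nn <- paste0("IkB", i, "n_NFkBn")
    K_I <- paste0("IKKa_IkB", i)
    K_I_N <- paste0("IKKa_IkB", i, "_NFkB")
    r <- c(r, list(
      rxn(paste0("IKKa + ", IkB, " -> IKKa:", IkB), paste0("A", i),
          c("IKKa", IkB),
          stats::setNames(c(-1, -1, 1), c("IKKa", IkB, K_I))),
      rxn(paste0("IKKa + ", IkB, ":NFkB -> IKKa:", IkB, ":NFkB"),
          paste0("B", i), c("IKKa", IkB_N),
          stats::setNames(c(-1, -1, 1), c("IKKa", IkB_N, K_I_N))),
      rxn(paste0("IKKa:", IkB, " -> IKKa + ", IkB), paste0("D", i), K_I,
          stats::setNames(c(-1, 1, 1), c(K_I, "IKKa", IkB))),
      rxn(paste0("IKKa:", IkB, ":NFkB -> IKKa + ", IkB, ":NFkB"),
          paste0("D", i), K_I_N,
          stats::setNames(c(-1, 1, 1), c(K_I_N, "IKKa", IkB_N))),
      rxn(paste0("IKKa:", IkB, ":NFkB -> IKKa:", IkB, " + NFkB"),
          paste0("E", i), K_I_N,
          stats::setNames(c(-1, 1, 1), c(K_I_N, K_I, "NFkB"))),
      rxn(paste0("IKKa:", IkB, " + NFkB -> IKKa:", IkB, ":NFkB"),
          paste0("F", i), c(K_I, "NFkB"),
          stats::setNames(c(-1, -1, 1), c(K_I, "NFkB", K_I_N))),
      rxn(paste0(IkB, ":NFkB -> NFkB + ", IkB), paste0("G", i), IkB_N,
          stats::setNames(c(-1, 1, 1), c(IkB_N, "NFkB", IkB))),
      rxn(paste0(IkBn, ":NFkBn -> NFkBn + ", IkBn), paste0("G", i), IkBn_Nn,
          stats::setNames(c(-1, 1, 1), c(IkBn_Nn, "NFkBn", IkBn))),
      rxn(paste0(IkB, " + NFkB -> ", IkB, ":NFkB"), paste0("H", i),
          c(IkB, "NFkB"),
          stats::setNames(c(-1, -1, 1), c(IkB, "NFkB", IkB_N))),
      rxn(paste0(IkBn, " + NFkBn -> ", IkBn, ":NFkBn"), paste0("H", i),
          c(IkBn, "NFkBn"),
          stats::setNames(c(-1, -1, 1), c(IkBn, "NFkBn", IkBn_Nn))),
      rxn(paste0(IkBn, ":NFkBn -> ", IkB, ":NFkB"), paste0("L", i), IkBn_Nn,
          stats::setNames(c(-1, 1), c(IkBn_Nn, IkB_N)), home = "cyt"),
      rxn(paste0(IkB, ":NFkB -> NFkB"), paste0("M", i), IkB_N,
          stats::setNames(c(-1, 1), c(IkB_N, "NFkB"))),
      rxn(paste0("IKKa:", IkB, ":NFkB -> IKKa + NFkB"), paste0("P", i),
          K_I_N, stats::setNames(c(-1, 1, 1), c(K_I_N, "IKKa", "NFkB"))),
      rxn(paste0(IkBn, " -> ", IkB), paste0("Q", i), IkBn,
          stats::setNames(c(-1, 1), c(IkBn, IkB)), home = "cyt"),
      rxn(paste0("IKKa:", IkB, " -> IKKa"), paste0("R", i), K_I,
          stats::setNames(c(-1, 1), c(K_I, "IKKa"))),
      rxn(paste0(IkBn, ":NFkBn -> NFkBn"), paste0("S", i), IkBn_Nn,
          stats::setNames(c(-1, 1), c(IkBn_Nn, "NFkBn"))),
      rxn(paste0("NFkBn -> NFkBn + ", IkBt), paste0("U", i), "NFkBn",
          stats::setNames(1, IkBt), home = "cyt"),
      rxn(paste0(IkB, " -> ", IkBn), paste0("V", i), IkB,
          stats::setNames(c(-1, 1), c(IkB, IkBn))),
      rxn(paste0(IkB, ", ", IkBn, " -> 0"), paste0("W", i), IkB,
          stats::setNames(-1, IkB)),
      rxn(paste0(IkB, ", ", IkBn, " -> 0"), paste0("W", i), IkBn,
          stats::setNames(-1, IkBn)),
      rxn(paste0(IkBt, " -> ", IkBt, " + ", IkB), paste0("X", i), IkBt,
          stats::setNames(1, IkB)),
      rxn(paste0("0 -> ", IkBt), paste0("Y", i), character(0),
          stats::setNames(1, IkBt)),
      rxn(paste0(IkBt, " -> 0"), paste0("Z", i), IkBt,
          stats::setNames(-1, IkBt))
    ))
  }
  r
}

#' Compile the reaction network for a parameter set
#'
#' Assembles the mass-action machinery: per-flux rate constants (with the
#' stimulus dosage `TR` folded into the IKKn -> IKKa activation flux), the
#' substrate index lists, and the stoichiometry matrix in triplet form.
#' Nucleo-cytoplasmic transport fluxes are written in cytoplasmic
#' concentration units in both directions (the convention of the model
#' lineage this network extends): the cytoplasmic species changes by the
#' plain mass-action flux while the nuclear species changes `Kv`-fold
#' faster, `Kv` being the cytoplasm:nucleus volume ratio. This conserves
#' molecule *amounts* exactly, so the volume-weighted total NF-kB is an
#' invariant of the dynamics.
#'
#' @param params An `nfkb_params` vector.
#' @param TR Dimensionless stimulus dosage (>= 0) multiplying the
#'   IKKn -> IKKa rate `K1`.
#' @return A list with elements `k`, `sub1`, `sub2` (1-based indices, 0 =
#'   none), `Si`, `Sj`, `Sx` (stoichiometry triplets), `species`, and
#'   `reactions` (tibble with `row`, `symbol`).
#' @keywords internal
#' @export
nfkb_model <- function(params, TR = 0) {
  stopifnot(inherits(params, "nfkb_params"), is.numeric(TR), TR >= 0)
  sp <- nfkb_species()
  spi <- stats::setNames(seq_len(nrow(sp)), sp$species)
  vol <- ifelse(sp$compartment == "cyt", params[["Kv"]], 1)
  rl <- nfkb_reaction_list()
  nr <- length(rl)

  k <- numeric(nr)
  sub1 <- integer(nr)
  sub2 <- integer(nr)
  Si <- integer(0); Sj <- integer(0); Sx <- numeric(0)
  rows <- character(nr); syms <- character(nr)

  for (j in seq_len(nr)) {
    rx <- rl[[j]]
    rows[j] <- rx$row
    syms[j] <- rx$sym
    kj <- params[[rx$sym]]
    if (rx$tr) kj <- kj * TR
    k[j] <- kj
    ns <- length(rx$subs)
    sub1[j] <- if (ns >= 1) spi[[rx$subs[[1]]]] else 0L
    sub2[j] <- if (ns >= 2) spi[[rx$subs[[2]]]] else 0L
    home <- rx$home
    if (is.null(home)) {
      home <- if (ns > 0 && all(sp$compartment[c(sub1[j], sub2[j])[seq_len(ns)]] == "nuc"))
        "nuc" else "cyt"
    }
    vhome <- if (home == "cyt") params[["Kv"]] else 1
    idx <- spi[names(rx$stoich)]
    Si <- c(Si, as.integer(idx))
    Sj <- c(Sj, rep(j, length(idx)))
    Sx <- c(Sx, unname(rx$stoich) * vhome / vol[idx])
  }

  list(
    k = k, sub1 = sub1, sub2 = sub2, Si = Si, Sj = Sj, Sx = Sx,
    species = sp$species,
    reactions = tibble::tibble(row = rows, symbol = syms)
  )
}

#' Initial (pre-equilibration) state
#'
#' All of NF-kB starts free in the cytoplasm at the conserved total
#' concentration; every other species starts at zero.
#'
#' @param params An `nfkb_params` vector.
#' @return Named numeric state vector in species order.
#' @export
nfkb_initial_state <- function(params) {
  sp <- nfkb_species()
  st <- stats::setNames(numeric(nrow(sp)), sp$species)
  st[["NFkB"]] <- params[["NFkB_total"]]
  st
}

#' Mass-action right-hand side (reference implementation)
#'
#' Evaluates d(state)/dt as stoichiometry x flux in plain R. The compiled
#' integrator uses the same reaction machinery; this function is the slow,
#' transparent reference used for cross-checks.
#'
#' @param state Named (or plain) numeric state vector in [nfkb_species()]
#'   order.
#' @param params An `nfkb_params` vector.
#' @param TR Stimulus dosage.
#' @param clamp_tol Negative values larger (more negative) than
#'   `-clamp_tol` are clamped to zero before flux evaluation; values beyond
#'   that raise an error.
#' @return Named numeric vector of time derivatives (per second).
#' @export
nfkb_derivatives <- function(state, params, TR = 0, clamp_tol = 1e-12) {
  m <- nfkb_model(params, TR)
  ns <- length(m$species)
  stopifnot(length(state) == ns, all(is.finite(state)))
  y <- as.numeric(state)
  if (any(y < -clamp_tol)) {
    bad <- m$species[y < -clamp_tol]
    stop("negative concentration beyond clamp tolerance: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- pmax(y, 0)
  v <- m$k
  has1 <- m$sub1 > 0
  v[has1] <- v[has1] * y[m$sub1[has1]]
  has2 <- m$sub2 > 0
  v[has2] <- v[has2] * y[m$sub2[has2]]
  dy <- numeric(ns)
  contrib <- m$Sx * v[m$Sj]
  for (t in seq_along(m$Si)) dy[m$Si[t]] <- dy[m$Si[t]] + contrib[t]
  stats::setNames(dy, m$species)
}

#' Volume-weighted total NF-kB of a state
#'
#' Sums the NF-kB content of all species, weighting nuclear species by
#' `1/Kv`, in cytoplasmic concentration units. The reaction network
#' neither creates nor destroys NF-kB, so this quantity is conserved along
#' every trajectory and equals `NFkB_total`.
#'
#' @param state State vector or trajectory matrix/tibble (rows = times).
#' @param params An `nfkb_params` vector.
#' @return Numeric scalar or vector of totals.
#' @export
nfkb_total <- function(state, params) {
  sp <- nfkb_species()
  w <- sp$nfkb_units * ifelse(sp$compartment == "nuc",
                              1 / params[["Kv"]], 1)
  if (is.data.frame(state)) {
    state <- as.matrix(state[, sp$species, drop = FALSE])
  }
  if (is.matrix(state)) {
    drop(state[, sp$species, drop = FALSE] %*% w)
  } else {
    sum(as.numeric(state[sp$species]) * w)
  }
}
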