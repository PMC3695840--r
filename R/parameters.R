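#' Kinetic parameter symbols of the NF-kB network model
#'
#' Returns the canonical symbol set of the model: per-isoform rate constants
#' (suffix `a`, `b`, `e` for the IkBalpha/beta/epsilon isoforms), the
#' IKK/A20 module constants, the cytoplasm-to-nucleus volume ratio `Kv`,
#' and the conserved total NF-kB concentration `NFkB_total`.
#'
#' @return Character vector of parameter symbols.
#' @export
nfkb_symbols <- function() {
  iso <- c("a", "b", "e")
  per_iso <- c("A", "B", "D", "E", "F", "G", "H", "L", "M", "P", "Q", "R",
               "S", "U", "V", "W", "X", "Y", "Z")
  c(
    paste0(rep(per_iso, each = 3), iso),
    paste0("C", 1:5),
    "I1", "K01", "K1", "K2", "K3", "Kprod", "Kdeg",
    "Kv", "NFkB_total"
  )
}

#' Read the packaged reaction/rate-constant table
#'
#' The package ships a transcription of the model's reaction table as TSV:
#' one row per reaction (plus the structural rows for `Kv` and
#' `NFkB_total`), with a nominal and a fitted value column. Shared symbols
#' (e.g. `Da`, `Ga`, `Ha`) appear on several reaction rows and must agree
#' in value.
#'
#' @param path Path to a table in the packaged format; defaults to the
#'   table shipped with the package.
#' @return A tibble with columns `reaction`, `symbol`, `order_class`,
#'   `nominal_value`, `source_ref`, `fitted_value`.
#' @export
nfkb_reaction_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reaction_table.tsv", package = "nfkbse",
                        mustWork = TRUE)
  }
  readr::read_tsv(
    path,
    col_types = readr::cols(
      reaction = readr::col_character(),
      symbol = readr::col_character(),
      order_class = readr::col_character(),
      nominal_value = readr::col_double(),
      source_ref = readr::col_character(),
      fitted_value = readr::col_double()
    )
  )
}

#' Load a parameter set from the packaged table
#'
#' Collapses the reaction table to one non-negative value per rate-constant
#' symbol. Rows sharing a symbol must agree within 1% relative (the table
#' prints one shared constant at two precisions); the first, highest-precision
#' occurrence is kept.
#'
#' @param column Which value column to use: `"fitted"` (default) or
#'   `"nominal"`.
#' @param table Optional table as returned by [nfkb_reaction_table()]
#'   (or a path to one).
#' @return A named numeric vector of class `nfkb_params` with exactly the
#'   symbols of [nfkb_symbols()].
#' @examples
#' p <- nfkb_parameters("fitted")
#' p[["Aa"]]   # 0.1813
#' p[["Kv"]]   # 5
#' @export
nfkb_parameters <- function(column = c("fitted", "nominal"), table = NULL) {
  column <- match.arg(column)
  if (is.null(table) || is.character(table)) {
    table <- nfkb_reaction_table(table)
  }
  col <- paste0(column, "_value")
  stopifnot(all(c("symbol", col) %in% names(table)))
  vals <- table[[col]]
  syms <- table[["symbol"]]

  out <- stats::setNames(numeric(0), character(0))
  for (i in seq_along(syms)) {
    s <- syms[[i]]
    v <- vals[[i]]
    if (is.na(v)) {
      stop("missing value for symbol '", s, "' in parameter table",
           call. = FALSE)
    }
    if (s %in% names(out)) {
      ref <- out[[s]]
      agree <- (ref == v) || (abs(v - ref) <= 0.01 * max(abs(ref), abs(v)))
      if (!agree) {
        stop("duplicate symbol '", s, "' with conflicting values (",
             ref, " vs ", v, ")", call. = FALSE)
      }
    } else {
      out[[s]] <- v
    }
  }

  expected <- nfkb_symbols()
  missing <- setdiff(expected, names(out))
  if (length(missing) > 0) {
    stop("parameter table is missing symbol(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(out), expected)
  if (length(extra) > 0) {
    stop("parameter table has unknown symbol(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- out[expected]
  validate_params(out)
  structure(out, class = c("nfkb_params", "numeric"))
}

validate_params <- function(params) {
  if (any(!is.finite(params))) {
    stop("non-finite parameter value(s)", call. = FALSE)
  }
  if (any(params < 0)) {
    stop("negative rate constant(s): ",
         paste(names(params)[params < 0], collapse = ", "), call. = FALSE)
  }
  if (params[["Kv"]] <= 0) stop("Kv must be > 0", call. = FALSE)
  if (params[["NFkB_total"]] <= 0) {
    stop("NFkB_total must be > 0", call. = FALSE)
  }
  invisible(params)
}

#' @export
print.nfkb_params <- function(x, ...) {
  cat("<nfkb_params> ", length(x), " kinetic constants\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Genes that can be knocked out
#' @return Character vector of knockout gene names.
#' @export
nfkb_genes <- function() c("IkBa", "IkBb", "IkBe", "A20")

#' Apply gene knockouts to a parameter set
#'
#' Knockouts zero the mRNA synthesis rates of the targeted gene: for an IkB
#' isoform both the NF-kB-induced (`U*`) and constitutive (`Y*`)
#' transcription rates; for A20 both the induced (`C1`) and constitutive
#' (`C2`) rates. All other parameters are untouched and the input is not
#' modified.
#'
#' @param params An `nfkb_params` vector.
#' @param genotype Character vector of genes to knock out, a subset of
#'   [nfkb_genes()]; `character(0)` (default) is the wild type.
#' @return A new `nfkb_params` vector.
#' @examples
#' p <- nfkb_parameters()
#' ko <- apply_knockout(p, c("IkBb", "IkBe"))
#' ko[["Ub"]]  # 0
#' @export
apply_knockout <- function(params, genotype = character(0)) {
  stopifnot(inherits(params, "nfkb_params"))
  genotype <- unique(as.character(genotype))
  unknown <- setdiff(genotype, nfkb_genes())
  if (length(unknown) > 0) {
    stop("unknown gene(s): ", paste(unknown, collapse = ", "),
         "; valid genes are ", paste(nfkb_genes(), collapse = ", "),
         call. = FALSE)
  }
  out <- params
  iso_suffix <- c(IkBa = "a", IkBb = "b", IkBe = "e")
  for (g in genotype) {
    if (g == "A20") {
      out[c("C1", "C2")] <- 0
    } else {
      sfx <- iso_suffix[[g]]
      out[paste0(c("U", "Y"), sfx)] <- 0
    }
  }
  out
}

#' Write a parameter set in the packaged table format
#'
#' Produces a TSV in the same format as the shipped table, with the given
#' values in the `fitted_value` column (the `nominal_value` column keeps the
#' shipped nominal values). [nfkb_parameters()] on the result round-trips
#' the values exactly.
#'
#' @param params An `nfkb_params` vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  stopifnot(inherits(params, "nfkb_params"))
  tab <- nfkb_reaction_table()
  tab$fitted_value <- unname(params[tab$symbol])
  readr::write_tsv(tab, path)
  invisible(path)
}
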