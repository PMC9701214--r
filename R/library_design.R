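# Degenerate-codon site-saturation library arithmetic: theoretical
# diversity by codon-table enumeration, fold coverage, and Poisson
# completeness under the uniform-abundance approximation.

DEGENERATE_LETTERS <- list(
  N = c("A", "C", "G", "T"),
  K = c("G", "T"),
  S = c("C", "G"),
  A = "A", C = "C", G = "G", T = "T"
)

#' Enumerate the codons of a degenerate scheme
#'
#' Expands a degenerate codon (e.g. `"NNK"`) into its concrete codons and
#' translates each with the standard genetic code.
#'
#' @param scheme A 3-letter degenerate codon using IUPAC letters
#'   `N`, `K`, `S`, `A`, `C`, `G`, `T`.
#' @return A tibble with columns `codon`, `amino_acid` (one-letter, `*` for
#'   stop).
#' @export
enumerate_codons <- function(scheme) {
  letters_ <- strsplit(toupper(scheme), "")[[1]]
  if (length(letters_) != 3 || !all(letters_ %in% names(DEGENERATE_LETTERS))) {
    stop("unknown degenerate scheme '", scheme, "'", call. = FALSE)
  }
  combos <- expand.grid(
    DEGENERATE_LETTERS[[letters_[1]]],
    DEGENERATE_LETTERS[[letters_[2]]],
    DEGENERATE_LETTERS[[letters_[3]]],
    stringsAsFactors = FALSE
  )
  codons <- paste0(combos[, 1], combos[, 2], combos[, 3])
  aa <- vapply(
    codons,
    function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
    character(1)
  )
  tibble::tibble(codon = codons, amino_acid = unname(aa))
}

#' Define a site-saturation library
#'
#' @param n_sites Number of randomized positions (>= 1).
#' @param scheme Degenerate codon scheme: `"NNK"`, `"NNS"`, or `"NNN"`.
#' @param transformants Optional number of independent transformants
#'   obtained (for coverage statistics).
#' @return A `library_design` list.
#' @export
library_design <- function(n_sites, scheme = c("NNK", "NNS", "NNN"),
                           transformants = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n_sites >= 1)
  if (!is.null(transformants) && transformants <= 0) {
    stop("transformants must be positive", call. = FALSE)
  }
  structure(
    list(
      n_sites = as.integer(n_sites), scheme = scheme,
      transformants = transformants
    ),
    class = "library_design"
  )
}

#' Theoretical diversity of a degenerate-codon library
#'
#' Per-site codon and amino-acid counts come from enumerating the scheme's
#' codon table; totals are per-site counts raised to the number of sites.
#' For NNK: 32 codons per site encoding all 20 amino acids with one stop
#' (TAG), so three sites give 20^3 = 8000 protein variants over 32^3 =
#' 32768 codon combinations.
#'
#' @param design A [library_design()].
#' @return A tibble with one row: `codon_combinations`,
#'   `protein_combinations`, `stop_containing_fraction` (probability a
#'   random clone carries at least one stop codon), plus the per-site
#'   counts `codons_per_site`, `amino_acids_per_site`, `stops_per_site`.
#' @export
theoretical_diversity <- function(design) {
  stopifnot(inherits(design, "library_design"))
  tab <- enumerate_codons(design$scheme)
  n_codons <- nrow(tab)
  n_stop <- sum(tab$amino_acid == "*")
  n_aa <- length(unique(tab$amino_acid[tab$amino_acid != "*"]))
  n <- design$n_sites
  tibble::tibble(
    scheme = design$scheme,
    n_sites = n,
    codons_per_site = n_codons,
    amino_acids_per_site = n_aa,
    stops_per_site = n_stop,
    codon_combinations = n_codons^n,
    protein_combinations = n_aa^n,
    stop_containing_fraction = 1 - ((n_codons - n_stop) / n_codons)^n
  )
}

#' Library coverage statistics under the Poisson approximation
#'
#' With `N` transformants sampled uniformly over `V` variants:
#' fold coverage is `N / V`; the expected fraction of variants observed at
#' least once is `1 - exp(-N/V)`; the probability the library is complete
#' (every variant observed) is `(1 - exp(-N/V))^V`. Protein-level
#' diversity is used by default (the usual benchmark for saturation
#' libraries); `level = "codon"` switches to codon combinations.
#'
#' @param design A [library_design()] with `transformants` set.
#' @param level `"protein"` (default) or `"codon"`.
#' @return A tibble with one row: `fold_coverage`,
#'   `expected_fraction_observed`, `p_complete`, plus `transformants` and
#'   `diversity`.
#' @export
coverage_stats <- function(design, level = c("protein", "codon")) {
  stopifnot(inherits(design, "library_design"))
  level <- match.arg(level)
  n <- design$transformants
  if (is.null(n)) stop("design has no transformant count", call. = FALSE)
  if (n <= 0) stop("transformants must be positive", call. = FALSE)
  div <- theoretical_diversity(design)
  v <- if (level == "protein") div$protein_combinations else div$codon_combinations
  frac <- 1 - exp(-n / v)
  tibble::tibble(
    level = level,
    transformants = n,
    diversity = v,
    fold_coverage = n / v,
    expected_fraction_observed = frac,
    p_complete = frac^v
  )
}
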