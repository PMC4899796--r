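#' Population with latent disease subtypes
#'
#' A population stratified by genotype, in which the disease comprises
#' several unobserved subtypes, each following its own gene-dosage risk
#' model: subtype `k` has baseline risk `baseline_k` for the aa genotype and
#' risk multiplied by `per_allele_k` for every copy of the A allele. The
#' point of the construct: marginalizing over subtypes can destroy the
#' gene-dosage pattern entirely, and even flip the apparent direction of
#' the allele effect, which is why a trend test tuned to heterogeneity pays
#' off.
#'
#' @param genotype_counts Population counts `(N_aa, N_Aa, N_AA)`.
#' @param subtypes A data frame with columns `baseline` (risk at aa) and
#'   `per_allele` (multiplicative risk factor per A allele); one row per
#'   subtype. An optional `subtype` column names them.
#' @return An object of class `subtype_population`.
#' @examples
#' pop <- subtype_population(
#'   genotype_counts = c(250000, 500000, 250000),
#'   subtypes = data.frame(baseline = c(0.0001, 0.0020),
#'                         per_allele = c(10, 0.5)))
#' subtype_population_summary(pop)
#' @export
subtype_population <- function(genotype_counts, subtypes) {
  if (length(genotype_counts) != 3L || any(genotype_counts < 0)) {
    abort("`genotype_counts` must be 3 non-negative population counts.")
  }
  if (!is.data.frame(subtypes) ||
      !all(c("baseline", "per_allele") %in% names(subtypes)) ||
      nrow(subtypes) < 1L) {
    abort("`subtypes` must be a data frame with columns baseline, per_allele.")
  }
  risks <- outer(subtypes$per_allele, 0:2, `^`) * subtypes$baseline
  if (any(risks < 0) || any(risks > 1)) {
    abort("a subtype risk leaves [0, 1] after per-allele scaling.")
  }
  structure(
    list(genotype_counts = setNames(as.numeric(genotype_counts), GENOTYPES),
         subtypes = tibble::tibble(
           subtype = subtypes$subtype %||% paste0("subtype_", seq_len(nrow(subtypes))),
           baseline = subtypes$baseline, per_allele = subtypes$per_allele),
         risks = risks),
    class = "subtype_population"
  )
}

#' Marginal genotype risks and subtype case shares
#'
#' Expected case counts are `N_i * risk_{ik}` per genotype and subtype.
#' The marginal genotype risk ignores the subtype labels (total expected
#' cases at genotype `i` over `N_i`); the case share of a subtype is its
#' expected case total over the grand total.
#'
#' @param pop A [subtype_population()].
#' @return A list with `expected_cases` (tibble, subtype x genotype),
#'   `marginal_risks` (named 3-vector) and `case_shares` (named vector
#'   summing to 1).
#' @export
subtype_population_summary <- function(pop) {
  stopifnot(inherits(pop, "subtype_population"))
  n_i <- pop$genotype_counts
  cases <- pop$risks * rep(n_i, each = nrow(pop$risks))
  marginal <- colSums(cases) / n_i
  shares <- rowSums(cases) / sum(cases)
  list(
    expected_cases = tibble::tibble(
      subtype = rep(pop$subtypes$subtype, times = 3L),
      genotype = rep(GENOTYPES, each = nrow(pop$subtypes)),
      expected_cases = as.vector(cases)),
    marginal_risks = setNames(marginal, GENOTYPES),
    case_shares = setNames(shares, pop$subtypes$subtype)
  )
}
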