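## Prevalence tables and gene-category enrichment built on the exact
## 2x2 engine.

#' One prevalence-table row
#'
#' @param gene gene symbol (or a set label).
#' @param carriers number of distinct carrier samples.
#' @param cohort_n carrier denominator (cohort size).
#' @return data frame row: gene, carriers, cohort_n, prevalence
#'   (percentage, two decimals).
#' @export
prevalence_row <- function(gene, carriers, cohort_n) {
  if (carriers < 0 || carriers > cohort_n)
    stop("carriers must lie in [0, cohort_n]")
  data.frame(gene = gene, carriers = as.integer(carriers),
             cohort_n = as.integer(cohort_n),
             prevalence = round(100 * carriers / cohort_n, 2),
             stringsAsFactors = FALSE)
}

# distinct carrier sample ids of qualifying variants in the listed genes
.carrier_ids <- function(classification, genes, group = c("cases", "controls")) {
  group <- match.arg(group)
  col <- if (group == "cases") "case_carrier_ids" else "control_carrier_ids"
  idx <- which(is_qualifying(classification) & classification$gene %in% genes)
  unique(unlist(classification[[col]][idx]))
}

#' Carrier prevalence of one gene
#'
#' A carrier is a sample with at least one qualifying (novel or rare,
#' unshared, functional) variant in the gene; prevalence is
#' 100 * carriers / cohort_n at two decimals.
#'
#' @param classification value of \code{\link{classify_cohort}}.
#' @param gene gene symbol; must occur in the classification table.
#' @param group \code{"cases"} or \code{"controls"}.
#' @param cohort_n carrier denominator.
#' @return a prevalence row (see \code{\link{prevalence_row}}).
#' @export
gene_prevalence <- function(classification, gene, group = "cases", cohort_n) {
  if (!gene %in% classification$gene)
    stop("unknown gene: ", gene)
  carriers <- length(.carrier_ids(classification, gene, group))
  prevalence_row(gene, carriers, cohort_n)
}

#' Carrier prevalence of a gene list (union of carriers)
#'
#' Counts distinct samples carrying a qualifying variant in any listed
#' gene — a sample with hits in two genes counts once, so the total is at
#' most the sum of the per-gene counts.
#'
#' @param classification value of \code{\link{classify_cohort}}.
#' @param genes character vector of gene symbols.
#' @param group \code{"cases"} or \code{"controls"}.
#' @param cohort_n carrier denominator.
#' @return a prevalence row labelled \code{"Total"}.
#' @export
prevalence_total <- function(classification, genes, group = "cases",
                             cohort_n) {
  carriers <- length(.carrier_ids(classification, genes, group))
  prevalence_row("Total", carriers, cohort_n)
}

#' Scale a control count to the case cohort size
#'
#' With unequal cohort sizes, raw per-group variant counts are not
#' comparable; this rescales a control count to a control cohort of the
#' same size as the case cohort.
#'
#' @param count control count.
#' @param n_cases,n_controls cohort sizes.
#' @return count * n_cases / n_controls.
#' @export
adjust_control_count <- function(count, n_cases, n_controls) {
  count * n_cases / n_controls
}

#' Enrichment of qualifying variants in a tagged gene sub-set
#'
#' Counts, per group, the distinct samples carrying a qualifying variant
#' in the genes bearing the sub-set tag (e.g. \code{stress_granule}),
#' reports carrier percentages at two decimals, and tests the 2x2 carrier
#' table exactly.
#'
#' @param classification value of \code{\link{classify_cohort}}.
#' @param panel validated panel data frame.
#' @param tag sub-set tag.
#' @param config an \code{\link{analysis_config}} (cohort sizes and test
#'   method).
#' @return list: tag, genes, per-group carrier counts and percentages, and
#'   the \code{fisher_result}.
#' @export
category_enrichment <- function(classification, panel, tag,
                                config = analysis_config()) {
  genes <- panel_subset_genes(panel, tag)
  if (length(genes) == 0)
    stop("no panel genes carry sub-set tag '", tag, "'")
  cc <- length(.carrier_ids(classification, genes, "cases"))
  kc <- length(.carrier_ids(classification, genes, "controls"))
  fr <- snp_carrier_test(cc, kc, config$n_cases, config$n_controls,
                         method = config$test_method)
  list(tag = tag, genes = genes,
       case_carriers = cc, control_carriers = kc,
       case_pct = round(100 * cc / config$n_cases, 2),
       control_pct = round(100 * kc / config$n_controls, 2),
       fisher = fr)
}
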