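## PolyPhen-weighted allele binning: collapse each sample's qualifying
## variants into one deleteriousness score, threshold it to define
## carriers, and compare carrier counts between cases and controls with
## the exact 2x2 engine.

#' Effective PolyPhen score of each variant under the configured policies
#'
#' Stopgain, stoploss and frameshift variants have no PolyPhen score; the
#' default policy scores them 1.0 (most damaging), configurable to 0.
#' Other unscored variants are downweighted to 0 by default, or excluded.
#'
#' @param variants annotated-variant data frame.
#' @param config an \code{\link{analysis_config}}.
#' @return numeric vector of scores (NA where the variant is excluded).
#' @export
effective_scores <- function(variants, config = analysis_config()) {
  s <- variants$polyphen_score
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("PolyPhen scores must lie in [0, 1]")
  lof <- variants$functional_class %in% c("stopgain", "stoploss", "frameshift")
  if (config$lof_score_policy == "damaging") {
    s[lof & is.na(s)] <- 1.0
  } else {
    s[lof & is.na(s)] <- 0
  }
  if (config$score_missing_policy == "zero") s[is.na(s)] <- 0
  s
}

#' Collapse one sample's variant scores into an individual score
#'
#' Mode \code{max} takes the maximum score (0 for an empty set, the
#' non-carrier); mode \code{sum} adds them.
#'
#' @param scores numeric vector of per-variant scores in [0, 1] for the
#'   sample's qualifying variants (NA values, from excluded variants, are
#'   dropped).
#' @param mode \code{"max"} or \code{"sum"}.
#' @return a single non-negative score.
#' @export
individual_score <- function(scores, mode = c("max", "sum")) {
  mode <- match.arg(mode)
  scores <- scores[!is.na(scores)]
  if (any(scores < 0 | scores > 1))
    stop("per-variant scores must lie in [0, 1]")
  if (length(scores) == 0) return(0)
  if (mode == "max") max(scores) else sum(scores)
}

#' Per-sample binned scores over a gene set
#'
#' For every sample, collects the effective scores of its qualifying
#' (novel or rare, shared-excluded) variants inside the gene set and
#' collapses them with \code{\link{individual_score}}.
#'
#' @param cohort the classified \code{cohort_data}.
#' @param classification value of \code{\link{classify_cohort}} on it.
#' @param genes character vector of gene symbols defining the set.
#' @param config an \code{\link{analysis_config}}.
#' @return named numeric vector, one score per sample.
#' @export
sample_scores <- function(cohort, classification, genes,
                          config = analysis_config()) {
  idx <- which(is_qualifying(classification) & classification$gene %in% genes)
  n <- nrow(cohort$samples)
  out <- numeric(n)
  names(out) <- cohort$samples$sample_id
  if (length(idx) == 0) return(out)
  s <- effective_scores(classification[idx, , drop = FALSE], config)
  carrier <- !is.na(cohort$genotypes[, idx, drop = FALSE]) &
    cohort$genotypes[, idx, drop = FALSE] >= 1
  sm <- carrier * rep(s, each = n)
  sm[!carrier] <- NA          # distinguish "no variant" from score 0
  if (config$aggregation_mode == "max") {
    out <- apply(cbind(0, sm), 1, max, na.rm = TRUE)
  } else {
    out <- rowSums(sm, na.rm = TRUE)
  }
  names(out) <- cohort$samples$sample_id
  out
}

#' PolyPhen-weighted burden test over a gene set
#'
#' Counts, per group, the samples whose binned score reaches the
#' "probably damaging" threshold (default 0.85) and tests the 2x2 carrier
#' table with \code{\link{fisher_exact}}. The default gene set is the
#' union of the known-ALS and associated panel categories, the genes with
#' a high prior for involvement in disease.
#'
#' @param cohort the classified \code{cohort_data}.
#' @param classification value of \code{\link{classify_cohort}}.
#' @param panel validated panel data frame.
#' @param config an \code{\link{analysis_config}}.
#' @param categories panel categories defining the gene set.
#' @param genes explicit gene set, overriding \code{categories}.
#' @return object of class \code{burden_result}: gene-set id, per-sample
#'   scores, per-group carrier counts and the \code{fisher_result}.
#' @export
burden_test <- function(cohort, classification, panel,
                        config = analysis_config(),
                        categories = c("known_als", "associated"),
                        genes = NULL) {
  if (is.null(genes)) {
    genes <- panel_genes(panel, categories)
    set_id <- paste(categories, collapse = "+")
  } else {
    set_id <- "custom"
  }
  if (length(genes) == 0)
    stop("burden test gene set is empty")
  scores <- sample_scores(cohort, classification, genes, config)
  carrier <- scores >= config$polyphen_threshold
  grp <- cohort$samples$group
  n_case <- sum(grp == "case")
  n_ctrl <- sum(grp == "control")
  cc <- sum(carrier[grp == "case"])
  kc <- sum(carrier[grp == "control"])
  fr <- fisher_exact(matrix(c(cc, kc, n_case - cc, n_ctrl - kc), nrow = 2),
                     method = config$test_method)
  structure(list(gene_set = set_id, genes = genes, scores = scores,
                 case_carriers = cc, control_carriers = kc,
                 n_cases = n_case, n_controls = n_ctrl, fisher = fr),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Allele-binning burden test over gene set '", x$gene_set, "' (",
      length(x$genes), " genes)\n", sep = "")
  cat(sprintf("carriers: %d/%d cases vs %d/%d controls\n",
              x$case_carriers, x$n_cases, x$control_carriers, x$n_controls))
  print(x$fisher)
  invisible(x)
}
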