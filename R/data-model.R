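## Shared data model: plain data.frames with documented columns, plus a
## light cohort container and the analysis configuration object.

FUNCTIONAL_CLASSES <- c("nonsynonymous", "stopgain", "stoploss",
                        "frameshift", "synonymous", "other")
QUALIFYING_CLASSES <- c("nonsynonymous", "stopgain", "stoploss", "frameshift")
PANEL_CATEGORIES   <- c("known_als", "associated", "trios", "rrm")

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "gene", "protein_change",
                     "functional_class", "in_dbsnp", "dbsnp_id",
                     "dbsnp_has_freq", "esp_freq", "kg_freq",
                     "polyphen_score", "polyphen_label", "sift_label",
                     "mutationtaster_label", "phylop_label")

QUALITY_COLUMNS <- c("dp", "qual", "qd", "fs", "haplotype_score", "mq",
                     "mq_rank_sum", "read_pos_rank_sum")

#' Variant identity key
#'
#' A variant is identified by (chrom, pos, ref, alt) after multi-allelic
#' decomposition; this is also the annotation join key.
#'
#' @param x data frame with columns chrom, pos, ref, alt.
#' @return character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Validate an annotated-variant table
#'
#' Checks column presence, the functional-class vocabulary, frequency and
#' score ranges, the dbSNP consistency rule (a frequency listing implies
#' database membership) and key uniqueness. Missing annotations are `NA`,
#' never 0: a database entry with frequency 0 still counts as present.
#'
#' @param variants data frame of annotated variants.
#' @return the validated data frame, invisibly augmented with defaults for
#'   any absent optional columns.
#' @export
validate_variants <- function(variants) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "functional_class")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("variant table lacks required columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(variants$functional_class), FUNCTIONAL_CLASSES)
  if (length(bad))
    stop("unknown functional class value(s): ", paste(bad, collapse = ", "))
  defaults <- list(protein_change = NA_character_, in_dbsnp = FALSE,
                   dbsnp_id = NA_character_, dbsnp_has_freq = FALSE,
                   esp_freq = NA_real_, kg_freq = NA_real_,
                   polyphen_score = NA_real_, polyphen_label = NA_character_,
                   sift_label = NA_character_,
                   mutationtaster_label = NA_character_,
                   phylop_label = NA_character_)
  for (nm in names(defaults)) {
    if (is.null(variants[[nm]])) variants[[nm]] <- defaults[[nm]]
    # all-absent columns read from TSV arrive as logical NA; coerce to the
    # declared column type
    variants[[nm]] <- if (is.character(defaults[[nm]]))
      as.character(variants[[nm]])
    else if (is.numeric(defaults[[nm]])) as.numeric(variants[[nm]])
    else as.logical(variants[[nm]])
  }
  variants$pos <- as.integer(variants$pos)
  for (nm in c("esp_freq", "kg_freq", "polyphen_score")) {
    v <- variants[[nm]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("'", nm, "' values must lie in [0, 1]")
  }
  if (any(variants$dbsnp_has_freq & !variants$in_dbsnp))
    stop("dbsnp_has_freq requires in_dbsnp")
  key <- variant_key(variants)
  if (anyDuplicated(key))
    stop("duplicate variant key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  variants[VARIANT_COLUMNS]
}

#' Assemble a cohort container
#'
#' Joins a sample manifest, an annotated variant table, a per-sample
#' allele-dosage matrix and per-site quality fields into one object.
#' Dosages are 0/1/2 copies of the alternate allele, `NA` for a missing
#' genotype (missing is not reference).
#'
#' @param samples manifest data frame (see \code{\link{read_manifest}}).
#' @param variants annotated variant data frame.
#' @param genotypes integer matrix, samples x variants.
#' @param site_quality data frame of per-variant site quality fields
#'   (columns dp, qual, qd, fs, haplotype_score, mq, mq_rank_sum,
#'   read_pos_rank_sum), or NULL for all-absent.
#' @return object of class \code{cohort_data}.
#' @export
cohort_data <- function(samples, variants, genotypes, site_quality = NULL) {
  variants <- validate_variants(variants)
  if (is.null(site_quality)) {
    site_quality <- as.data.frame(
      matrix(NA_real_, nrow(variants), length(QUALITY_COLUMNS),
             dimnames = list(NULL, QUALITY_COLUMNS)))
  }
  if (nrow(genotypes) != nrow(samples))
    stop("genotype matrix rows (", nrow(genotypes),
         ") do not match sample count (", nrow(samples), ")")
  if (ncol(genotypes) != nrow(variants))
    stop("genotype matrix columns (", ncol(genotypes),
         ") do not match variant count (", nrow(variants), ")")
  if (nrow(site_quality) != nrow(variants))
    stop("site_quality rows do not match variant count")
  if (any(!is.na(genotypes) & !(genotypes %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(!samples$group %in% c("case", "control")))
    stop("sample group must be 'case' or 'control'")
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- samples$sample_id
  structure(list(samples = samples, variants = variants,
                 genotypes = genotypes, site_quality = site_quality),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat("cohort_data:", nrow(x$samples), "samples (",
      sum(x$samples$group == "case"), "cases,",
      sum(x$samples$group == "control"), "controls ),",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Restrict a cohort to a subset of its variants
#'
#' @param cohort a \code{cohort_data} object.
#' @param idx logical or integer index over variants.
#' @return a \code{cohort_data} with the selected variant columns.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cohort_data"))
  cohort$variants <- cohort$variants[idx, , drop = FALSE]
  rownames(cohort$variants) <- NULL
  cohort$genotypes <- cohort$genotypes[, idx, drop = FALSE]
  cohort$site_quality <- cohort$site_quality[idx, , drop = FALSE]
  rownames(cohort$site_quality) <- NULL
  cohort
}

#' Analysis configuration
#'
#' Collects every threshold of the analysis. Defaults are the study
#' constants: the ESP6500 rarity cutoff 0.000538 (the database frequency of
#' the pathogenic SOD1 p.D91A allele), the 1000 Genomes cutoff 0.01, the
#' PolyPhen-2 "probably damaging" carrier threshold 0.85, and the GATK-style
#' site hard-filter thresholds (fail when DP < 5, QUAL < 30, QD < 2,
#' FS > 50, HaplotypeScore > 13, MQ < 30, MQRankSum < -12.5,
#' ReadPosRankSum < -8; absent fields never fail).
#'
#' @param rarity_cutoff inclusive ESP6500 frequency cutoff for rarity.
#' @param kg_cutoff exclusive 1000 Genomes frequency cutoff used for
#'   dbSNP-listed variants without an ESP entry.
#' @param polyphen_threshold per-individual score at or above which a
#'   sample counts as a deleterious-variant carrier.
#' @param aggregation_mode how a sample's variant scores collapse to one
#'   score: \code{"max"} (default) or \code{"sum"}.
#' @param test_method two-sided exact-test convention, \code{"minlike"}
#'   (default) or \code{"central"}.
#' @param score_missing_policy PolyPhen score for variants without one:
#'   \code{"zero"} (default, downweighted to 0) or \code{"exclude"}.
#' @param lof_score_policy score for stopgain/stoploss/frameshift variants,
#'   which PolyPhen does not score: \code{"damaging"} (default, 1.0) or
#'   \code{"zero"}.
#' @param dp_min,qual_min,qd_min,fs_max,haplotype_score_max,mq_min,mq_rank_sum_min,read_pos_rank_sum_min
#'   site hard-filter thresholds.
#' @param n_cases,n_controls cohort sizes used as carrier denominators.
#' @param random_seed integer seed for any randomized step.
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(rarity_cutoff = 0.000538,
                            kg_cutoff = 0.01,
                            polyphen_threshold = 0.85,
                            aggregation_mode = c("max", "sum"),
                            test_method = c("minlike", "central"),
                            score_missing_policy = c("zero", "exclude"),
                            lof_score_policy = c("damaging", "zero"),
                            dp_min = 5.0, qual_min = 30.0, qd_min = 2.0,
                            fs_max = 50.0, haplotype_score_max = 13.0,
                            mq_min = 30.0, mq_rank_sum_min = -12.5,
                            read_pos_rank_sum_min = -8.0,
                            n_cases = 242L, n_controls = 129L,
                            random_seed = 1L) {
  cfg <- list(rarity_cutoff = rarity_cutoff, kg_cutoff = kg_cutoff,
              polyphen_threshold = polyphen_threshold,
              aggregation_mode = match.arg(aggregation_mode),
              test_method = match.arg(test_method),
              score_missing_policy = match.arg(score_missing_policy),
              lof_score_policy = match.arg(lof_score_policy),
              dp_min = dp_min, qual_min = qual_min, qd_min = qd_min,
              fs_max = fs_max, haplotype_score_max = haplotype_score_max,
              mq_min = mq_min, mq_rank_sum_min = mq_rank_sum_min,
              read_pos_rank_sum_min = read_pos_rank_sum_min,
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              random_seed = as.integer(random_seed))
  for (nm in c("rarity_cutoff", "kg_cutoff", "polyphen_threshold"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]")
  if (cfg$n_cases <= 0 || cfg$n_controls <= 0)
    stop("cohort sizes must be positive")
  structure(cfg, class = "analysis_config")
}

#' Validate a gene-panel table
#'
#' Every panel gene carries one or more of the four design categories
#' (known_als, associated, trios, rrm) and optionally sub-set tags such as
#' stress_granule; categories and subsets are comma-separated in the table.
#'
#' @param panel data frame with columns gene, categories and optionally
#'   subsets, rvis.
#' @return validated panel data frame.
#' @export
validate_panel <- function(panel) {
  if (is.null(panel) || nrow(panel) == 0)
    stop("panel must be non-empty")
  if (!all(c("gene", "categories") %in% names(panel)))
    stop("panel table needs columns 'gene' and 'categories'")
  if (is.null(panel$subsets)) panel$subsets <- ""
  if (is.null(panel$rvis)) panel$rvis <- NA_real_
  panel$subsets[is.na(panel$subsets)] <- ""
  cats <- strsplit(panel$categories, ",", fixed = TRUE)
  if (any(lengths(cats) == 0) || any(is.na(panel$categories)) ||
      any(panel$categories == ""))
    stop("every panel gene needs at least one category")
  bad <- setdiff(unique(unlist(cats)), PANEL_CATEGORIES)
  if (length(bad))
    stop("unknown panel categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(panel$gene))
    stop("duplicated panel gene(s)")
  panel[c("gene", "categories", "subsets", "rvis")]
}

#' Genes of a panel belonging to any of the given categories
#'
#' @param panel validated panel data frame.
#' @param categories character vector of category labels.
#' @return character vector of gene symbols.
#' @export
panel_genes <- function(panel, categories) {
  panel <- validate_panel(panel)
  hit <- vapply(strsplit(panel$categories, ",", fixed = TRUE),
                function(cs) any(cs %in% categories), logical(1))
  panel$gene[hit]
}

#' Genes of a panel carrying a sub-set tag
#'
#' @param panel validated panel data frame.
#' @param tag sub-set tag, e.g. \code{"stress_granule"}.
#' @return character vector of gene symbols.
#' @export
panel_subset_genes <- function(panel, tag) {
  panel <- validate_panel(panel)
  hit <- vapply(strsplit(panel$subsets, ",", fixed = TRUE),
                function(ts) any(ts %in% tag), logical(1))
  panel$gene[hit]
}
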