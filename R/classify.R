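## Site quality filtering and novel/rare classification with the shared
## case-control exclusion.

#' Apply the site hard filters
#'
#' A site fails when any of: DP < 5, QUAL < 30, QD < 2, FS > 50,
#' HaplotypeScore > 13, MQ < 30, MQRankSum < -12.5, ReadPosRankSum < -8
#' (strict comparators; thresholds configurable). A field that is absent
#' never fails its rule.
#'
#' @param site_quality data frame of site-quality fields (one row per site).
#' @param config an \code{\link{analysis_config}}.
#' @return data frame with logical \code{pass} and comma-separated
#'   \code{reasons} listing the failed rules.
#' @export
apply_quality_filters <- function(site_quality, config = analysis_config()) {
  q <- site_quality
  fail_low <- function(v, thr) !is.na(v) & v < thr
  fail_high <- function(v, thr) !is.na(v) & v > thr
  rules <- cbind(DP = fail_low(q$dp, config$dp_min),
                 QUAL = fail_low(q$qual, config$qual_min),
                 QD = fail_low(q$qd, config$qd_min),
                 FS = fail_high(q$fs, config$fs_max),
                 HaplotypeScore = fail_high(q$haplotype_score,
                                            config$haplotype_score_max),
                 MQ = fail_low(q$mq, config$mq_min),
                 MQRankSum = fail_low(q$mq_rank_sum, config$mq_rank_sum_min),
                 ReadPosRankSum = fail_low(q$read_pos_rank_sum,
                                           config$read_pos_rank_sum_min))
  reasons <- apply(rules, 1, function(r)
    paste(colnames(rules)[r], collapse = ","))
  data.frame(pass = rowSums(rules) == 0, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Is a variant novel?
#'
#' Novel means absent from all three databases: not in dbSNP, no ESP6500
#' frequency and no 1000 Genomes frequency. A database listing with
#' frequency 0 counts as present.
#'
#' @param variants annotated-variant data frame.
#' @return logical vector.
#' @export
is_novel <- function(variants) {
  !variants$in_dbsnp & is.na(variants$esp_freq) & is.na(variants$kg_freq)
}

#' Is a database-known variant rare?
#'
#' Rare means ESP6500 frequency at or below the cutoff (default 0.000538,
#' inclusive), or listed in dbSNP without a frequency, absent from ESP6500,
#' and either absent from 1000 Genomes or there below 0.01 (exclusive).
#' Applies only to database-known variants; calling it on a novel variant
#' is a contract error.
#'
#' @param variants annotated-variant data frame.
#' @param config an \code{\link{analysis_config}}.
#' @return logical vector.
#' @export
is_rare <- function(variants, config = analysis_config()) {
  if (any(is_novel(variants)))
    stop("is_rare() applies only to database-known variants; ",
         "filter out novel variants first")
  esp_rare <- !is.na(variants$esp_freq) &
    variants$esp_freq <= config$rarity_cutoff
  dbsnp_rare <- variants$in_dbsnp & !variants$dbsnp_has_freq &
    is.na(variants$esp_freq) &
    (is.na(variants$kg_freq) | variants$kg_freq < config$kg_cutoff)
  esp_rare | dbsnp_rare
}

#' Restrict to functional (protein-altering) variants
#'
#' Keeps nonsynonymous, stopgain, stoploss and frameshift variants; drops
#' synonymous and other classes. Synonymous SNPs remain available to the
#' SNP-association step, which works from the full variant set.
#'
#' @param variants annotated-variant data frame.
#' @return the functional subset.
#' @export
restrict_functional <- function(variants) {
  variants[variants$functional_class %in% QUALIFYING_CLASSES, , drop = FALSE]
}

#' Classify every variant of a cohort
#'
#' Assumes quality filtering and the functional restriction have been
#' applied (see \code{\link{classify_variants}} for the full chain).
#' Carrier counts use dosage >= 1; missing genotypes never count as
#' carriage. Statuses:
#' \describe{
#'   \item{novel / rare}{qualifying variant carried by one group only,
#'     attributed to that group;}
#'   \item{excluded_shared}{novel or rare variant carried by at least one
#'     case and at least one control — removed as a likely benign
#'     polymorphism;}
#'   \item{common}{database-known above the rarity rules.}
#' }
#'
#' @param cohort a \code{cohort_data}.
#' @param config an \code{\link{analysis_config}}.
#' @return data frame: the cohort's variant table plus \code{status},
#'   \code{reasons}, \code{group} (cases/controls/NA), per-group carrier
#'   counts and per-group carrier sample-id lists (list columns
#'   \code{case_carrier_ids}, \code{control_carrier_ids}).
#' @export
classify_cohort <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "cohort_data"))
  v <- cohort$variants
  carrier <- !is.na(cohort$genotypes) & cohort$genotypes >= 1
  case_rows <- cohort$samples$group == "case"
  cc <- colSums(carrier[case_rows, , drop = FALSE])
  kc <- colSums(carrier[!case_rows, , drop = FALSE])
  ids <- cohort$samples$sample_id

  novel <- is_novel(v)
  rare <- logical(nrow(v))
  rare[!novel] <- is_rare(v[!novel, , drop = FALSE], config)

  status <- rep("common", nrow(v))
  reasons <- rep("database_frequency_above_cutoff", nrow(v))
  status[rare] <- "rare"
  reasons[rare] <- "database_frequency_at_or_below_cutoff"
  status[novel] <- "novel"
  reasons[novel] <- "absent_from_all_databases"
  shared <- (novel | rare) & cc >= 1 & kc >= 1
  status[shared] <- "excluded_shared"
  reasons[shared] <- paste0(reasons[shared], ",carried_in_both_groups")

  group <- rep(NA_character_, nrow(v))
  qual <- status %in% c("novel", "rare")
  group[qual & cc >= 1] <- "cases"
  group[qual & kc >= 1 & cc == 0] <- "controls"

  out <- v
  out$status <- status
  out$reasons <- reasons
  out$group <- group
  out$case_carriers <- as.integer(cc)
  out$control_carriers <- as.integer(kc)
  out$case_carrier_ids <- lapply(seq_len(ncol(carrier)), function(j)
    ids[case_rows & carrier[, j]])
  out$control_carrier_ids <- lapply(seq_len(ncol(carrier)), function(j)
    ids[!case_rows & carrier[, j]])
  class(out) <- c("cohort_classification", class(out))
  out
}

#' Quality filter, functional restriction and classification in one step
#'
#' Runs the full variant-level chain on a cohort and keeps per-stage
#' bookkeeping: sites read, failing quality, non-functional, then the
#' classification of the remainder.
#'
#' @param cohort a \code{cohort_data}.
#' @param config an \code{\link{analysis_config}}.
#' @return list with \code{classification} (see
#'   \code{\link{classify_cohort}}), \code{cohort} (the filtered cohort)
#'   and \code{counts}, a named vector of per-stage record counts.
#' @export
classify_variants <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "cohort_data"))
  qf <- apply_quality_filters(cohort$site_quality, config)
  kept_q <- subset_cohort(cohort, qf$pass)
  functional <- kept_q$variants$functional_class %in% QUALIFYING_CLASSES
  kept_f <- subset_cohort(kept_q, functional)
  cls <- classify_cohort(kept_f, config)
  counts <- c(sites_read = nrow(cohort$variants),
              failed_quality = sum(!qf$pass),
              non_functional = sum(!functional),
              novel = sum(cls$status == "novel"),
              rare = sum(cls$status == "rare"),
              excluded_shared = sum(cls$status == "excluded_shared"),
              common = sum(cls$status == "common"),
              novel_cases = sum(cls$status == "novel" &
                                  cls$group == "cases", na.rm = TRUE),
              novel_controls = sum(cls$status == "novel" &
                                     cls$group == "controls", na.rm = TRUE),
              rare_cases = sum(cls$status == "rare" &
                                 cls$group == "cases", na.rm = TRUE),
              rare_controls = sum(cls$status == "rare" &
                                    cls$group == "controls", na.rm = TRUE))
  list(classification = cls, cohort = kept_f, counts = counts)
}

#' Qualifying (novel or rare, unshared) variant indicator
#'
#' @param classification value of \code{\link{classify_cohort}}.
#' @return logical vector over variants.
#' @export
is_qualifying <- function(classification) {
  classification$status %in% c("novel", "rare")
}
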