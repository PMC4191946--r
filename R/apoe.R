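## APOE epsilon-diplotype calling from the two coding SNPs and the
## stratified phenotype associations.
##
## The three epsilon alleles are haplotypes of rs429358 (p.C130R) and
## rs7412 (p.R176C): e3 is wild type at both positions, e4 carries C130R,
## e2 carries R176C. A haplotype carrying both changes (the rare e1) is
## not modelled.

# dosage pair -> diplotype lookup; key "d130,d176"
.apoe_map <- list(
  "0,0" = c("e3", "e3"), "0,1" = c("e2", "e3"), "0,2" = c("e2", "e2"),
  "1,0" = c("e3", "e4"), "2,0" = c("e4", "e4"), "1,1" = c("e2", "e4"))

#' Call APOE epsilon diplotypes from the two SNP dosages
#'
#' \code{genotype_130} is the alternate-allele dosage of the p.C130R
#' change (rs429358), \code{genotype_176} of p.R176C (rs7412). Phase is
#' resolved so the two changes never share a haplotype when avoidable;
#' the double heterozygote is therefore called e2/e4 and flagged
#' ambiguous (the e2/e4 phase overwhelmingly dominates in the population;
#' the alternative would require an e1 allele). Dosage pairs (2,1), (1,2)
#' and (2,2) would force an e1 haplotype and are a data error. Missing
#' dosages give an uncallable sample, excluded from denominators.
#'
#' @param genotype_130,genotype_176 integer dosages in 0..2 (NA = missing),
#'   recycled to a common length.
#' @param sample_id optional sample identifiers.
#' @return data frame: sample_id, allele1, allele2 (sorted), ambiguous,
#'   callable.
#' @export
call_apoe <- function(genotype_130, genotype_176, sample_id = NULL) {
  n <- max(length(genotype_130), length(genotype_176))
  d130 <- rep_len(as.integer(genotype_130), n)
  d176 <- rep_len(as.integer(genotype_176), n)
  if (is.null(sample_id)) sample_id <- as.character(seq_len(n))
  ok <- !is.na(d130) & !is.na(d176)
  if (any(ok & (d130 < 0 | d130 > 2 | d176 < 0 | d176 > 2)))
    stop("APOE dosages must lie in 0..2")
  impossible <- ok & (d130 + d176 > 2)
  if (any(impossible))
    stop("impossible APOE dosage pair(s) (would require an e1 haplotype) ",
         "for sample(s): ",
         paste(sample_id[impossible], collapse = ", "))
  allele1 <- rep(NA_character_, n)
  allele2 <- rep(NA_character_, n)
  for (i in which(ok)) {
    al <- .apoe_map[[paste(d130[i], d176[i], sep = ",")]]
    allele1[i] <- al[1]
    allele2[i] <- al[2]
  }
  data.frame(sample_id = sample_id, allele1 = allele1, allele2 = allele2,
             ambiguous = ok & d130 == 1L & d176 == 1L,
             callable = ok, stringsAsFactors = FALSE)
}

#' Carriers of an epsilon allele
#'
#' Carrier means at least one copy; uncallable samples are NA.
#'
#' @param diplotypes value of \code{\link{call_apoe}}.
#' @param allele \code{"e2"}, \code{"e3"} or \code{"e4"}.
#' @return logical vector.
#' @export
apoe_carrier <- function(diplotypes, allele = c("e2", "e3", "e4")) {
  allele <- match.arg(allele)
  out <- diplotypes$allele1 == allele | diplotypes$allele2 == allele
  out[!diplotypes$callable] <- NA
  out
}

#' Exact test of an epsilon allele against a phenotype stratum
#'
#' Builds the 2x2 table of allele carriage (>= 1 copy) against membership
#' of a manifest stratum (e.g. \code{onset_site == "upper_limb"}) over a
#' chosen sample subset (by default the cases), and tests it exactly.
#' Uncallable samples are excluded. An empty stratum level gives a
#' degenerate (zero-margin) result, not an error.
#'
#' @param diplotypes value of \code{\link{call_apoe}}, aligned with
#'   \code{samples}.
#' @param samples manifest data frame.
#' @param allele epsilon allele whose carriage is tested.
#' @param stratum_field manifest column name (\code{onset_site},
#'   \code{sex} or \code{long_survivor}).
#' @param stratum_level value of that column defining the stratum.
#' @param subset logical vector selecting the samples entering the test
#'   (default: cases only).
#' @param method two-sided exact-test convention.
#' @return list: descriptors, 2x2 table and the \code{fisher_result}.
#' @export
apoe_strata_test <- function(diplotypes, samples, allele,
                             stratum_field = "onset_site",
                             stratum_level = "upper_limb",
                             subset = samples$group == "case",
                             method = c("minlike", "central")) {
  if (!stratum_field %in% names(samples))
    stop("unknown manifest field: ", stratum_field)
  carrier <- apoe_carrier(diplotypes, allele)
  in_stratum <- samples[[stratum_field]] == stratum_level
  keep <- subset & !is.na(carrier)
  tb <- matrix(c(sum(keep & carrier & in_stratum),
                 sum(keep & !carrier & in_stratum),
                 sum(keep & carrier & !in_stratum),
                 sum(keep & !carrier & !in_stratum)), nrow = 2)
  list(allele = allele, stratum_field = stratum_field,
       stratum_level = stratum_level, table = tb,
       fisher = fisher_exact(tb, method = match.arg(method)))
}

#' The standard battery of APOE phenotype tests
#'
#' Runs, over the cases: e2 carriage vs upper-limb onset, e4 carriage vs
#' bulbar onset, e2 carriage vs the long-survivor panel, and e4 carriage
#' vs sex within limb-onset cases; plus e4 carriage cases vs controls.
#' Also summarises age of onset by e4 carriage (medians only).
#'
#' @param diplotypes value of \code{\link{call_apoe}}, aligned with
#'   \code{samples}.
#' @param samples manifest data frame.
#' @param method two-sided exact-test convention.
#' @return named list of stratum-test results plus
#'   \code{age_of_onset_medians}.
#' @export
apoe_strata_tests <- function(diplotypes, samples,
                              method = c("minlike", "central")) {
  method <- match.arg(method)
  cases <- samples$group == "case"
  limb_cases <- cases & samples$onset_site %in% c("limb", "upper_limb")
  e4 <- apoe_carrier(diplotypes, "e4")
  res <- list(
    e2_upper_limb = apoe_strata_test(diplotypes, samples, "e2",
                                     "onset_site", "upper_limb",
                                     subset = cases, method = method),
    e4_bulbar = apoe_strata_test(diplotypes, samples, "e4",
                                 "onset_site", "bulbar",
                                 subset = cases, method = method),
    e2_long_survivor = apoe_strata_test(diplotypes, samples, "e2",
                                        "long_survivor", TRUE,
                                        subset = cases, method = method),
    e4_female_limb = apoe_strata_test(diplotypes, samples, "e4",
                                      "sex", "female",
                                      subset = limb_cases, method = method),
    e4_case_control = apoe_strata_test(diplotypes, samples, "e4",
                                       "group", "case",
                                       subset = rep(TRUE, nrow(samples)),
                                       method = method))
  keep <- cases & !is.na(e4) & !is.na(samples$age_of_onset)
  res$age_of_onset_medians <- c(
    e4_carrier = stats::median(samples$age_of_onset[keep & e4]),
    non_carrier = stats::median(samples$age_of_onset[keep & !e4]))
  res
}
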