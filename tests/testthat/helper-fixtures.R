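# Fixtures are constructed in code at test time.

# annotated-variant rows with overridable fields
make_variants <- function(n = 1, ...) {
  df <- data.frame(
    chrom = "chr1", pos = seq_len(n) * 100L, ref = "A", alt = "G",
    gene = "GENE001", protein_change = NA_character_,
    functional_class = "nonsynonymous",
    in_dbsnp = FALSE, dbsnp_id = NA_character_, dbsnp_has_freq = FALSE,
    esp_freq = NA_real_, kg_freq = NA_real_,
    polyphen_score = NA_real_, polyphen_label = NA_character_,
    sift_label = NA_character_, mutationtaster_label = NA_character_,
    phylop_label = NA_character_, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# quality rows that pass every hard filter unless overridden
make_quality <- function(n = 1, ...) {
  df <- data.frame(dp = 100, qual = 500, qd = 20, fs = 1,
                   haplotype_score = 2, mq = 60, mq_rank_sum = 0,
                   read_pos_rank_sum = 0)[rep(1, n), , drop = FALSE]
  rownames(df) <- NULL
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_manifest <- function(n_cases, n_controls) {
  data.frame(
    sample_id = c(sprintf("CASE%03d", seq_len(n_cases)),
                  sprintf("CTRL%03d", seq_len(n_controls))),
    group = rep(c("case", "control"), c(n_cases, n_controls)),
    sex = "unknown", onset_site = "unknown", age_of_onset = NA_real_,
    long_survivor = FALSE, stringsAsFactors = FALSE)
}

# cohort from a variants table and an explicit dosage matrix
# (rows = samples)
make_cohort <- function(variants, genotypes, n_cases, n_controls,
                        quality = NULL) {
  cohort_data(make_manifest(n_cases, n_controls), variants, genotypes,
              quality)
}

# hand-written three-sample VCF with one multi-allelic record and one
# missing genotype / absent INFO record
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Float,Description=\"depth\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qual by depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", ".", "A", "G", "500", "PASS", "DP=50;QD=20", "GT",
          "0/1", "0/0", "1/1", sep = "\t"),
    paste("1", "200", ".", "C", "A,T", "300", "PASS", "DP=40", "GT",
          "1/2", "0/1", "2/2", sep = "\t"),
    paste("1", "300", ".", "G", "T", ".", "PASS", ".", "GT",
          "./.", "0/1", "0/0", sep = "\t")), path)
  path
}

# independent enumeration oracle for exact 2x2 p-values: point
# probabilities from the factorial formula, tails by explicit summation
oracle_pvalues <- function(m1, m2, n1) {
  N <- m1 + m2
  sup <- max(0, n1 - m2):min(n1, m1)
  lp <- lfactorial(m1) - lfactorial(sup) - lfactorial(m1 - sup) +
    lfactorial(m2) - lfactorial(n1 - sup) - lfactorial(m2 - n1 + sup) +
    lfactorial(n1) + lfactorial(N - n1) - lfactorial(N)
  p <- exp(lp)
  p <- p / sum(p)
  minlike <- numeric(length(sup))
  central <- numeric(length(sup))
  for (i in seq_along(sup)) {
    minlike[i] <- sum(p[p <= p[i] * (1 + 1e-7)])
    lo <- sum(p[sup <= sup[i]])
    hi <- sum(p[sup >= sup[i]])
    central[i] <- min(1, 2 * min(lo, hi))
  }
  data.frame(x = sup, minlike = pmin(1, minlike), central = central)
}

# first-principles re-derivation of classify_cohort on a small cohort:
# set operations over genotype columns
oracle_classify <- function(cohort, config = analysis_config()) {
  v <- cohort$variants
  out <- character(nrow(v))
  for (j in seq_len(nrow(v))) {
    row <- v[j, ]
    novel <- !row$in_dbsnp && is.na(row$esp_freq) && is.na(row$kg_freq)
    rare <- FALSE
    if (!novel) {
      if (!is.na(row$esp_freq)) {
        rare <- row$esp_freq <= config$rarity_cutoff
      } else if (row$in_dbsnp && !row$dbsnp_has_freq) {
        rare <- is.na(row$kg_freq) || row$kg_freq < config$kg_cutoff
      }
    }
    g <- cohort$genotypes[, j]
    in_case <- any(g[cohort$samples$group == "case"] >= 1, na.rm = TRUE)
    in_ctrl <- any(g[cohort$samples$group == "control"] >= 1, na.rm = TRUE)
    out[j] <- if ((novel || rare) && in_case && in_ctrl) "excluded_shared"
    else if (novel) "novel" else if (rare) "rare" else "common"
  }
  out
}
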