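## Readers and writers for the external file formats: multi-sample VCF
## (via vcfR), and the tab-separated annotation / manifest / panel /
## frequency-database / result tables. "." or an empty cell means absent.

# numeric columns are serialized at full precision so that write + read
# round-trips exactly
write_tsv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]))
      out[[nm]] <- ifelse(is.na(out[[nm]]),
                          NA_character_,
                          formatC(out[[nm]], digits = 17, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", na.strings = c(".", "", "NA"),
                    stringsAsFactors = FALSE, ...)
}

#' Read a multi-sample VCF
#'
#' Parses a VCFv4 file (via the vcfR package), decomposes multi-allelic
#' records into one entry per alternate allele, computes per-sample allele
#' dosages from the GT field, and extracts the site-quality INFO fields
#' (DP, QD, FS, HaplotypeScore, MQ, MQRankSum, ReadPosRankSum) and the QUAL
#' column. Coordinates stay 1-based. A missing genotype (\code{./.}) gives
#' dosage \code{NA}; absent INFO keys give absent quality fields.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @return list with elements \code{sample_ids} (from the header),
#'   \code{sites} (data frame chrom/pos/ref/alt), \code{genotypes}
#'   (samples x decomposed-variants dosage matrix) and \code{site_quality}.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  gt_raw <- vcf@gt
  sample_ids <- colnames(gt_raw)[-1]
  # GT is the leading colon-separated field per VCF spec; vcfR reports a
  # fully missing genotype as NA
  gt <- sub(":.*$", "", gt_raw[, -1, drop = FALSE])
  gt[is.na(gt)] <- "."

  allele_lists <- strsplit(gt, "[/|]")
  bad <- !vapply(allele_lists, function(a)
    length(a) >= 1 && all(a %in% c(".", as.character(0:9))), logical(1))
  if (any(bad)) {
    rec <- ((which(bad)[1] - 1) %% n_rec) + 1
    stop("malformed GT field in VCF record ", rec, " (", fix[rec, "CHROM"],
         ":", fix[rec, "POS"], ")")
  }

  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  info_num <- function(key) {
    v <- suppressWarnings(vcfR::extract.info(vcf, element = key,
                                             as.numeric = TRUE))
    if (is.null(v)) rep(NA_real_, n_rec) else as.numeric(v)
  }
  qual_rec <- data.frame(dp = info_num("DP"), qual = qual,
                         qd = info_num("QD"), fs = info_num("FS"),
                         haplotype_score = info_num("HaplotypeScore"),
                         mq = info_num("MQ"),
                         mq_rank_sum = info_num("MQRankSum"),
                         read_pos_rank_sum = info_num("ReadPosRankSum"))

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_out <- sum(lengths(alts))
  sites <- data.frame(chrom = rep(fix[, "CHROM"], lengths(alts)),
                      pos = rep(as.integer(fix[, "POS"]), lengths(alts)),
                      ref = rep(fix[, "REF"], lengths(alts)),
                      alt = unlist(alts),
                      stringsAsFactors = FALSE)
  key <- variant_key(sites)
  if (anyDuplicated(key))
    stop("duplicate site after decomposition: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))

  geno <- matrix(NA_integer_, length(sample_ids), n_out,
                 dimnames = list(sample_ids, NULL))
  dim(allele_lists) <- dim(gt)
  col <- 0L
  for (r in seq_len(n_rec)) {
    rec_alleles <- allele_lists[r, ]
    missing_gt <- vapply(rec_alleles, function(a) any(a == "."), logical(1))
    for (j in seq_along(alts[[r]])) {
      col <- col + 1L
      dos <- vapply(rec_alleles, function(a) sum(a == as.character(j)), 0L)
      dos[missing_gt] <- NA_integer_
      geno[, col] <- dos
    }
  }
  site_quality <- qual_rec[rep(seq_len(n_rec), lengths(alts)), , drop = FALSE]
  rownames(site_quality) <- NULL
  list(sample_ids = sample_ids, sites = sites, genotypes = geno,
       site_quality = site_quality)
}

#' Read an annotation table
#'
#' Tab-separated, one row per (chrom, pos, ref, alt): gene, protein change,
#' functional class, database memberships and population frequencies, and
#' in-silico pathogenicity annotations (consumed, never computed). Empty
#' frequency cells become absent (`NA`), never 0.
#'
#' @param path path to the annotation TSV.
#' @return validated annotated-variant data frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path)
  for (nm in c("in_dbsnp", "dbsnp_has_freq"))
    if (!is.null(df[[nm]])) df[[nm]] <- as.logical(df[[nm]])
  validate_variants(df)
}

#' Read a sample manifest
#'
#' Columns: sample_id, group (case/control), sex (female/male/unknown),
#' onset_site (bulbar/upper_limb/limb/unknown), age_of_onset (years, absent
#' for controls), long_survivor (TRUE for the seven-year-plus survival
#' panel). Controls must have unknown onset site and no age of onset.
#'
#' @param path path to the manifest TSV.
#' @return validated manifest data frame.
#' @export
read_manifest <- function(path) {
  df <- read_tsv(path, colClasses = c(sample_id = "character"))
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest manifest data frame to validate in place.
#' @export
validate_manifest <- function(manifest) {
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(manifest))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(manifest$sex)) manifest$sex <- "unknown"
  if (is.null(manifest$onset_site)) manifest$onset_site <- "unknown"
  if (is.null(manifest$age_of_onset)) manifest$age_of_onset <- NA_real_
  if (is.null(manifest$long_survivor)) manifest$long_survivor <- FALSE
  manifest$long_survivor <- as.logical(manifest$long_survivor)
  if (any(!manifest$group %in% c("case", "control")))
    stop("manifest group must be 'case' or 'control'")
  if (any(!manifest$sex %in% c("female", "male", "unknown")))
    stop("manifest sex must be female/male/unknown")
  if (any(!manifest$onset_site %in%
          c("bulbar", "upper_limb", "limb", "unknown")))
    stop("manifest onset_site must be bulbar/upper_limb/limb/unknown")
  ctrl <- manifest$group == "control"
  if (any(ctrl & manifest$onset_site != "unknown"))
    stop("controls must have onset_site 'unknown'")
  if (any(ctrl & !is.na(manifest$age_of_onset)))
    stop("controls must not carry an age of onset")
  if (anyDuplicated(manifest$sample_id))
    stop("duplicated sample_id in manifest")
  manifest[c("sample_id", "group", "sex", "onset_site", "age_of_onset",
             "long_survivor")]
}

#' Read a gene-panel definition
#'
#' Tab-separated with columns gene, categories (comma-separated over
#' known_als/associated/trios/rrm), and optional subsets (comma-separated
#' tags such as stress_granule) and rvis.
#'
#' @param path path to the panel TSV.
#' @return validated panel data frame.
#' @export
read_panel <- function(path) {
  df <- tryCatch(read_tsv(path), error = function(e)
    stop("panel must be non-empty"))
  validate_panel(df)
}

#' Read a population-frequency database table
#'
#' One row per known site: chrom, pos, ref, alt, in_dbsnp, dbsnp_id,
#' dbsnp_has_freq, esp_freq, kg_freq.
#'
#' @param path path to the frequency TSV.
#' @return data frame of database sites.
#' @export
read_freqdb <- function(path) {
  df <- read_tsv(path)
  for (nm in c("in_dbsnp", "dbsnp_has_freq"))
    if (!is.null(df[[nm]])) df[[nm]] <- as.logical(df[[nm]])
  df
}

#' Assemble a cohort from VCF, annotation and manifest inputs
#'
#' Joins the decomposed VCF sites to the annotation table by
#' (chrom, pos, ref, alt) and the VCF samples to the manifest. Every VCF
#' sample must appear in the manifest and every site must be annotated.
#'
#' @param vcf value of \code{\link{read_vcf}}.
#' @param annotations annotated-variant data frame.
#' @param manifest validated manifest data frame.
#' @return a \code{\link{cohort_data}} object, samples ordered as in the
#'   manifest (restricted to samples present in the VCF).
#' @export
assemble_cohort <- function(vcf, annotations, manifest) {
  manifest <- validate_manifest(manifest)
  missing_samples <- setdiff(vcf$sample_ids, manifest$sample_id)
  if (length(missing_samples))
    stop("sample(s) in VCF missing from manifest: ",
         paste(missing_samples, collapse = ", "))
  manifest <- manifest[manifest$sample_id %in% vcf$sample_ids, , drop = FALSE]
  rownames(manifest) <- NULL

  annotations <- validate_variants(annotations)
  akey <- variant_key(annotations)
  vkey <- variant_key(vcf$sites)
  idx <- match(vkey, akey)
  if (anyNA(idx))
    stop("unannotated site(s): ", paste(vkey[is.na(idx)], collapse = ", "))
  variants <- annotations[idx, , drop = FALSE]
  rownames(variants) <- NULL

  geno <- vcf$genotypes[match(manifest$sample_id, vcf$sample_ids), ,
                        drop = FALSE]
  cohort_data(manifest, variants, geno, vcf$site_quality)
}

#' Write the per-variant result table
#'
#' One row per variant with its identity key, gene, annotations,
#' classification status and reasons, and per-group carrier counts.
#' Writing then reading reproduces the table exactly.
#'
#' @param records classification data frame (see
#'   \code{\link{classify_cohort}}).
#' @param path output TSV path.
#' @export
write_variant_table <- function(records, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "gene", "protein_change",
                      "functional_class", "status", "reasons", "group",
                      "case_carriers", "control_carriers", "esp_freq",
                      "kg_freq", "polyphen_score", "polyphen_label"),
                    names(records))
  write_tsv(records[cols], path)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  read_tsv(path)
}

#' Write a cohort as a multi-sample VCF
#'
#' Emits a minimal VCFv4.2 file with GT genotypes and the site-quality
#' INFO keys used by the hard filters. One biallelic record per variant.
#'
#' @param cohort a \code{cohort_data} object.
#' @param path output path.
#' @export
write_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_data"))
  v <- cohort$variants
  q <- cohort$site_quality
  info_fields <- c(dp = "DP", qd = "QD", fs = "FS",
                   haplotype_score = "HaplotypeScore", mq = "MQ",
                   mq_rank_sum = "MQRankSum",
                   read_pos_rank_sum = "ReadPosRankSum")
  header <- c("##fileformat=VCFv4.2",
              "##source=raveburden",
              sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                      info_fields, names(info_fields)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$samples$sample_id),
                    collapse = "\t"))
  info <- vapply(seq_len(nrow(v)), function(i) {
    vals <- unlist(q[i, names(info_fields)])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(paste0(info_fields[keep], "=",
                 trimws(formatC(vals[keep], digits = 10, format = "g"))),
          collapse = ";")
  }, "")
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[cohort$genotypes + 1L],
                   nrow = nrow(cohort$genotypes))
  gt_chr[is.na(gt_chr)] <- "./."
  body <- paste(v$chrom, v$pos,
                ifelse(is.na(v$dbsnp_id), ".", v$dbsnp_id),
                v$ref, v$alt,
                ifelse(is.na(q$qual), ".",
                       trimws(formatC(q$qual, digits = 10, format = "g"))),
                "PASS", info, "GT",
                apply(gt_chr, 2, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
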