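test_that("VCF parsing decomposes multi-allelic records with hand-checked dosages", {
  path <- write_fixture_vcf(tempfile(fileext = ".vcf"))
  v <- read_vcf(path)
  expect_identical(v$sample_ids, c("S1", "S2", "S3"))
  expect_identical(variant_key(v$sites),
                   c("1:100:A:G", "1:200:C:A", "1:200:C:T", "1:300:G:T"))
  expect_identical(unname(v$genotypes[, 1]), c(1L, 0L, 2L))
  # record C>A,T: S1 is 1/2 (one copy of each), S2 0/1, S3 2/2
  expect_identical(unname(v$genotypes[, 2]), c(1L, 1L, 0L))
  expect_identical(unname(v$genotypes[, 3]), c(1L, 0L, 2L))
  expect_identical(unname(v$genotypes[, 4]), c(NA_integer_, 1L, 0L))
  expect_equal(v$site_quality$dp, c(50, 40, 40, NA))
  expect_equal(v$site_quality$qd, c(20, NA, NA, NA))
  expect_equal(v$site_quality$qual, c(500, 300, 300, NA))
  # decomposition preserves the total alternate-allele count per record:
  # GTs 1/2, 0/1, 2/2 carry five alternate alleles
  expect_equal(sum(v$genotypes[, 2:3]), 5)
})

test_that("VCF dosage sums match an independent line-by-line GT scan", {
  cfg <- sim_config(n_genes = 10, missing_rate = 0.05)
  st <- simulate_study(cfg, seed = 11, dir = tempfile())
  v <- read_vcf(st$files[["vcf"]])
  lines <- readLines(st$files[["vcf"]])
  body <- lines[!startsWith(lines, "#")]
  scan_sums <- vapply(body, function(l) {
    gts <- strsplit(l, "\t")[[1]][-(1:9)]
    sum(vapply(gts, function(g)
      sum(strsplit(g, "/")[[1]] == "1"), 0)[gts != "./."])
  }, 0, USE.NAMES = FALSE)
  expect_equal(unname(colSums(v$genotypes, na.rm = TRUE)), scan_sums)
})

test_that("malformed and duplicate VCF records are reported", {
  path <- tempfile(fileext = ".vcf")
  base <- readLines(write_fixture_vcf(tempfile(fileext = ".vcf")))
  writeLines(sub("0/1\t0/0\t1/1", "0/x\t0/0\t1/1", base), path)
  expect_error(read_vcf(path), "malformed GT")
  dup <- c(base, paste("1", "100", ".", "A", "G", "11", "PASS", ".", "GT",
                       "0/0", "0/0", "0/0", sep = "\t"))
  writeLines(dup, path)
  expect_error(read_vcf(path), "duplicate site")
})

test_that("annotation reading keeps absent frequencies absent", {
  path <- tempfile(fileext = ".tsv")
  df <- make_variants(3,
                      gene = c("SOD1", "GENE002", "GENE003"),
                      protein_change = c("p.D91A", NA, NA),
                      in_dbsnp = c(TRUE, FALSE, FALSE),
                      dbsnp_has_freq = c(TRUE, FALSE, FALSE),
                      esp_freq = c(0.000538, NA, NA),
                      polyphen_score = c(0.99, NA, 0.5),
                      polyphen_label = c("D", NA, "P"))
  raveburden:::write_tsv(df, path)
  back <- read_annotations(path)
  expect_identical(back$esp_freq, c(0.000538, NA, NA))
  expect_identical(back$polyphen_score[1], 0.99)
  expect_identical(back$polyphen_label[1], "D")
  expect_true(all(is.na(back$esp_freq[2:3])))

  df$functional_class[2] <- "weird"
  raveburden:::write_tsv(df, path)
  expect_error(read_annotations(path), "weird")
})

test_that("variant validation enforces the documented invariants", {
  expect_error(validate_variants(make_variants(1, esp_freq = 1.5)),
               "\\[0, 1\\]")
  expect_error(validate_variants(
    make_variants(1, dbsnp_has_freq = TRUE, in_dbsnp = FALSE)),
    "dbsnp_has_freq")
  two <- make_variants(2, pos = c(100L, 100L))
  expect_error(validate_variants(two), "duplicate")
})

test_that("manifest reading validates groups and control phenotype rules", {
  m <- make_manifest(242, 129)
  path <- tempfile(fileext = ".tsv")
  raveburden:::write_tsv(m, path)
  back <- read_manifest(path)
  expect_equal(sum(back$group == "case"), 242)
  expect_equal(sum(back$group == "control"), 129)

  bad <- m
  bad$onset_site[bad$group == "control"][1] <- "bulbar"
  raveburden:::write_tsv(bad, path)
  expect_error(read_manifest(path), "controls")

  bad <- m
  bad$age_of_onset[bad$group == "control"][1] <- 60
  raveburden:::write_tsv(bad, path)
  expect_error(read_manifest(path), "controls")
})

test_that("panel reading handles multi-category genes and rejects empty panels", {
  path <- tempfile(fileext = ".tsv")
  pan <- data.frame(gene = c("FUS", "APOE"),
                    categories = c("known_als,rrm", "associated"),
                    subsets = c("stress_granule", ""),
                    rvis = c(-1.2, NA))
  raveburden:::write_tsv(pan, path)
  back <- read_panel(path)
  expect_setequal(panel_genes(back, "known_als"), "FUS")
  expect_setequal(panel_genes(back, "rrm"), "FUS")
  expect_setequal(panel_genes(back, c("known_als", "associated")),
                  c("FUS", "APOE"))
  expect_identical(panel_subset_genes(back, "stress_granule"), "FUS")

  writeLines("gene\tcategories", path)
  expect_error(read_panel(path), "non-empty")
  pan$categories[2] <- "nonsense"
  raveburden:::write_tsv(pan, path)
  expect_error(read_panel(path), "unknown panel categories")
})

test_that("cohort assembly cross-validates samples and annotations", {
  vpath <- write_fixture_vcf(tempfile(fileext = ".vcf"))
  v <- read_vcf(vpath)
  ann <- make_variants(4, chrom = "1", pos = c(100L, 200L, 200L, 300L),
                       ref = c("A", "C", "C", "G"),
                       alt = c("G", "A", "T", "T"))
  man <- data.frame(sample_id = c("S1", "S2", "S3"),
                    group = c("case", "case", "control"),
                    stringsAsFactors = FALSE)
  co <- assemble_cohort(v, ann, man)
  expect_s3_class(co, "cohort_data")
  expect_equal(dim(co$genotypes), c(3, 4))

  expect_error(assemble_cohort(v, ann, man[1:2, ]),
               "missing from manifest: S3")
  expect_error(assemble_cohort(v, ann[1:3, ], man), "unannotated")
})

test_that("the variant result table round-trips through write and read", {
  cfg <- sim_config(n_genes = 8)
  st <- simulate_study(cfg, seed = 5)
  cls <- classify_variants(st$cohort)$classification
  path <- tempfile(fileext = ".tsv")
  write_variant_table(cls, path)
  back <- read_variant_table(path)
  for (nm in c("chrom", "pos", "ref", "alt", "gene", "status",
               "case_carriers", "control_carriers", "esp_freq",
               "polyphen_score"))
    expect_equal(back[[nm]], cls[[nm]], info = nm)
})
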