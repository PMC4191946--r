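test_that("hard filters use the documented strict comparators", {
  cfg <- analysis_config()
  q <- make_quality(1, dp = 4)
  r <- apply_quality_filters(q, cfg)
  expect_false(r$pass)
  expect_identical(r$reasons, "DP")

  expect_true(apply_quality_filters(make_quality(1), cfg)$pass)
  # boundary values sit exactly on the thresholds and must pass
  expect_true(apply_quality_filters(
    make_quality(1, dp = 5, qual = 30, qd = 2, fs = 50,
                 haplotype_score = 13, mq = 30, mq_rank_sum = -12.5,
                 read_pos_rank_sum = -8), cfg)$pass)
  # absent fields never fail their rule
  expect_true(apply_quality_filters(
    make_quality(1, qd = NA, fs = NA, haplotype_score = NA, mq = NA,
                 mq_rank_sum = NA, read_pos_rank_sum = NA), cfg)$pass)

  multi <- apply_quality_filters(make_quality(1, fs = 80, mq = 10), cfg)
  expect_false(multi$pass)
  expect_identical(multi$reasons, "FS,MQ")
})

test_that("novelty means absence from all three databases", {
  v <- make_variants(4,
                     in_dbsnp = c(FALSE, TRUE, FALSE, FALSE),
                     esp_freq = c(NA, NA, NA, 0.2),
                     kg_freq = c(NA, NA, 0.3, NA))
  expect_identical(is_novel(v), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("rarity applies the inclusive ESP and exclusive 1000G boundaries", {
  cfg <- analysis_config()
  v <- make_variants(6,
                     in_dbsnp = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                     dbsnp_has_freq = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                        FALSE),
                     esp_freq = c(0.000538, 0.000625, NA, NA, NA, NA),
                     kg_freq = c(NA, NA, 0.009, 0.01, NA, 0.3))
  r <- is_rare(v, cfg)
  expect_identical(r, c(TRUE,   # at the anchor frequency: inclusive
                        FALSE,  # just above the cutoff
                        TRUE,   # dbSNP no-frequency, 1000G below 0.01
                        FALSE,  # 1000G exactly 0.01: exclusive
                        TRUE,   # dbSNP no-frequency, absent from 1000G
                        FALSE)) # 1000G-only listing
  # lowering the cutoff never adds rare variants
  tighter <- is_rare(v, analysis_config(rarity_cutoff = 0.0004))
  expect_true(all(!r | !tighter | tighter == r))
  expect_true(sum(tighter) <= sum(r))
  # contract: novel variants must not reach is_rare
  expect_error(is_rare(make_variants(1), cfg), "novel")
})

test_that("the functional restriction keeps protein-altering classes", {
  v <- make_variants(6, functional_class = c("nonsynonymous", "stopgain",
                                             "stoploss", "frameshift",
                                             "synonymous", "other"))
  kept <- restrict_functional(v)
  expect_setequal(kept$functional_class,
                  c("nonsynonymous", "stopgain", "stoploss", "frameshift"))
  expect_identical(nrow(restrict_functional(v[0, ])), 0L)
})

test_that("classification attributes variants and excludes shared ones", {
  # variant 1: novel, 2 cases + 1 control (the shared-exclusion pattern)
  # variant 2: novel, 1 case; variant 3: rare, 1 control; variant 4: common
  v <- make_variants(4,
                     in_dbsnp = c(FALSE, FALSE, TRUE, TRUE),
                     dbsnp_has_freq = c(FALSE, FALSE, TRUE, TRUE),
                     esp_freq = c(NA, NA, 0.0004, 0.2))
  g <- matrix(0L, 5, 4)
  g[1, 1] <- 1L; g[2, 1] <- 1L; g[4, 1] <- 1L   # samples 4,5 are controls
  g[1, 2] <- 1L
  g[5, 3] <- 2L
  g[, 4] <- 1L
  co <- make_cohort(v, g, 3, 2)
  cls <- classify_cohort(co)
  expect_identical(cls$status,
                   c("excluded_shared", "novel", "rare", "common"))
  expect_identical(cls$group, c(NA, "cases", "controls", NA))
  expect_identical(cls$case_carriers, c(2L, 1L, 0L, 3L))
  expect_identical(cls$control_carriers, c(1L, 0L, 1L, 2L))
  expect_identical(cls$case_carrier_ids[[2]], "CASE001")
  # partition: exactly one status each, novel and rare disjoint
  expect_true(all(table(cls$status) >= 0))
  expect_length(intersect(which(cls$status == "novel"),
                          which(cls$status == "rare")), 0)
})

test_that("missing genotypes never count as carriage", {
  v <- make_variants(1)
  g <- matrix(c(NA_integer_, 0L, 0L), 3, 1)
  cls <- classify_cohort(make_cohort(v, g, 2, 1))
  expect_identical(cls$case_carriers, 0L)
  expect_identical(cls$status, "novel")
  expect_true(is.na(cls$group))
})

test_that("classification matches a first-principles oracle on random cohorts", {
  set.seed(101)
  for (rep in 1:8) {
    n_v <- sample(5:20, 1)
    in_db <- sample(c(TRUE, FALSE), n_v, replace = TRUE)
    has_fr <- in_db & sample(c(TRUE, FALSE), n_v, replace = TRUE)
    esp <- ifelse(has_fr & runif(n_v) < 0.7,
                  runif(n_v, 0, 0.002), NA_real_)
    kg <- ifelse(runif(n_v) < 0.3, runif(n_v, 0, 0.05), NA_real_)
    in_db <- in_db | !is.na(esp)          # keep the membership invariant
    v <- make_variants(n_v, in_dbsnp = in_db, dbsnp_has_freq = has_fr & in_db,
                       esp_freq = esp, kg_freq = kg)
    g <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), 8 * n_v, replace = TRUE),
                8, n_v)
    co <- make_cohort(v, g, 5, 3)
    cls <- classify_cohort(co)
    expect_identical(cls$status, oracle_classify(co))
    # idempotence: reclassifying the same cohort changes nothing
    expect_identical(classify_cohort(co)$status, cls$status)
  }
})

test_that("functional restriction and shared-exclusion commute", {
  set.seed(77)
  n_v <- 30
  v <- make_variants(n_v,
                     functional_class = sample(
                       c("nonsynonymous", "synonymous", "stopgain"),
                       n_v, replace = TRUE))
  g <- matrix(sample(c(0L, 0L, 1L), 10 * n_v, replace = TRUE), 10, n_v)
  co <- make_cohort(v, g, 6, 4)
  # restrict first, classify second
  keep <- co$variants$functional_class %in%
    c("nonsynonymous", "stopgain", "stoploss", "frameshift")
  a <- classify_cohort(subset_cohort(co, keep))
  # classify first, restrict second
  b <- classify_cohort(co)
  b <- b[b$functional_class %in%
           c("nonsynonymous", "stopgain", "stoploss", "frameshift"), ]
  expect_identical(a$status, b$status)
})

test_that("the staged chain keeps consistent per-stage counts", {
  st <- simulate_study(sim_config(n_genes = 12), seed = 4)
  cl <- classify_variants(st$cohort)
  ct <- cl$counts
  expect_equal(ct[["sites_read"]],
               ct[["failed_quality"]] + ct[["non_functional"]] +
                 ct[["novel"]] + ct[["rare"]] + ct[["excluded_shared"]] +
                 ct[["common"]])
  expect_equal(nrow(cl$classification), nrow(cl$cohort$variants))
})
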