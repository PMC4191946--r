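test_that("individual scores collapse by max or sum", {
  expect_equal(individual_score(c(0.99, 0.12), "max"), 0.99)
  expect_equal(individual_score(numeric(0), "max"), 0)
  expect_equal(individual_score(numeric(0), "sum"), 0)
  # two possibly-damaging variants cross 0.85 under sum but not max
  expect_equal(individual_score(c(0.5, 0.5), "sum"), 1.0)
  expect_equal(individual_score(c(0.5, 0.5), "max"), 0.5)
  expect_error(individual_score(c(0.5, 1.2), "max"), "\\[0, 1\\]")
})

test_that("score policies handle unscored and truncating variants", {
  v <- make_variants(3, functional_class = c("nonsynonymous", "stopgain",
                                             "nonsynonymous"),
                     polyphen_score = c(0.4, NA, NA))
  cfg <- analysis_config()
  expect_equal(effective_scores(v, cfg), c(0.4, 1.0, 0))
  expect_equal(effective_scores(v, analysis_config(
    lof_score_policy = "zero")), c(0.4, 0, 0))
  expect_equal(effective_scores(v, analysis_config(
    score_missing_policy = "exclude")), c(0.4, 1.0, NA))
})

# small cohort: 3 cases, 2 controls; two genes; variant scores chosen so
# max- and sum-aggregation differ
.burden_fixture <- function() {
  v <- make_variants(4, gene = c("G1", "G1", "G2", "G1"),
                     polyphen_score = c(0.9, 0.5, 0.5, 0.95))
  g <- matrix(0L, 5, 4)
  g[1, 1] <- 1L               # case 1: score 0.9 in G1
  g[2, 2] <- 1L; g[2, 3] <- 1L  # case 2: 0.5 + 0.5 across G1, G2
  g[4, 4] <- 2L               # control 1: 0.95
  co <- make_cohort(v, g, 3, 2)
  pan <- data.frame(gene = c("G1", "G2"),
                    categories = c("known_als", "associated"),
                    subsets = "", rvis = NA_real_)
  list(cohort = co, cls = classify_cohort(co), panel = pan)
}

test_that("burden carriers depend on the aggregation mode as documented", {
  fx <- .burden_fixture()
  bmax <- burden_test(fx$cohort, fx$cls, fx$panel)
  expect_equal(bmax$case_carriers, 1)
  expect_equal(bmax$control_carriers, 1)
  expect_equal(unname(bmax$scores), c(0.9, 0.5, 0, 0.95, 0))

  bsum <- burden_test(fx$cohort, fx$cls, fx$panel,
                      analysis_config(aggregation_mode = "sum"))
  expect_equal(bsum$case_carriers, 2)   # 0.5 + 0.5 now crosses 0.85
  expect_equal(unname(bsum$scores), c(0.9, 1.0, 0, 0.95, 0))
})

test_that("burden test validates its gene set and handles zero carriers", {
  fx <- .burden_fixture()
  expect_error(burden_test(fx$cohort, fx$cls, fx$panel, genes = character(0)),
               "empty")
  high <- burden_test(fx$cohort, fx$cls, fx$panel,
                      analysis_config(polyphen_threshold = 1))
  expect_equal(high$case_carriers + high$control_carriers, 0)
  expect_true(high$fisher$degenerate)
  expect_equal(high$fisher$p_two_sided, 1)
})

test_that("max-mode carriers equal brute-force per-sample carrier status", {
  set.seed(12)
  for (thr in c(0.5, 0.85, 0.95)) {
    cfg <- analysis_config(polyphen_threshold = thr)
    st <- simulate_study(sim_config(n_genes = 10), seed = 31)
    cl <- classify_variants(st$cohort, cfg)
    b <- burden_test(cl$cohort, cl$classification, st$panel, cfg)
    # brute force: a carrier has >= 1 qualifying variant scoring >= thr
    cls <- cl$classification
    idx <- which(is_qualifying(cls) & cls$gene %in% b$genes)
    sc <- effective_scores(cls[idx, ], cfg)
    carrier <- vapply(seq_len(nrow(cl$cohort$samples)), function(i) {
      gi <- cl$cohort$genotypes[i, idx]
      any(!is.na(gi) & gi >= 1 & sc >= thr)
    }, logical(1))
    grp <- cl$cohort$samples$group
    expect_equal(b$case_carriers, sum(carrier[grp == "case"]))
    expect_equal(b$control_carriers, sum(carrier[grp == "control"]))
  }
})

test_that("raising the threshold never increases carrier counts", {
  st <- simulate_study(sim_config(n_genes = 10), seed = 13)
  cl <- classify_variants(st$cohort)
  thr <- c(0.2, 0.5, 0.85, 0.99)
  carriers <- vapply(thr, function(t) {
    b <- burden_test(cl$cohort, cl$classification, st$panel,
                     analysis_config(polyphen_threshold = t))
    b$case_carriers + b$control_carriers
  }, 0)
  expect_true(all(diff(carriers) <= 0))
})

test_that("the anchor carrier table reproduces the two-group layout", {
  r <- snp_carrier_test(10, 1, 242, 129)
  expect_identical(r$table, matrix(c(10, 1, 232, 128), 2))
  expect_equal(r$p_two_sided, 0.106, tolerance = 5e-3)
})
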