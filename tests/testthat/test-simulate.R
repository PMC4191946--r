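test_that("default panel mirrors the study design", {
  pan <- simulate_panel(sim_config(), seed = 1)
  expect_equal(nrow(pan), 169)
  expect_true(all(nzchar(pan$categories)))
  expect_true("APOE" %in% panel_genes(pan, "associated"))
  expect_equal(length(panel_genes(pan, "known_als")), 22)
  # multi-category genes exist (known ALS genes containing an RRM)
  expect_true(any(grepl("known_als,rrm", pan$categories)))
  expect_gt(length(panel_subset_genes(pan, "stress_granule")), 1)
})

test_that("identical seeds reproduce identical studies", {
  cfg <- sim_config(n_genes = 15)
  a <- simulate_study(cfg, seed = 9)
  b <- simulate_study(cfg, seed = 9)
  expect_identical(a$panel, b$panel)
  expect_identical(a$freqdb, b$freqdb)
  expect_identical(unclass(a$cohort), unclass(b$cohort))
  c2 <- simulate_study(cfg, seed = 10)
  expect_false(identical(a$cohort$genotypes, c2$cohort$genotypes))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_study(sim_config(n_genes = 5), seed = 2))
  expect_identical(runif(1), before)
})

test_that("the site catalog exercises every classification rule", {
  cfg <- sim_config(n_genes = 20)
  pan <- simulate_panel(cfg, 1)
  fdb <- simulate_freqdb(pan, cfg, 1)
  # the anchor sits exactly at the cutoff and classifies rare
  anchor <- fdb[fdb$site_type == "anchor", ]
  expect_equal(anchor$esp_freq, 0.000538)
  expect_true(is_rare(anchor[, raveburden:::VARIANT_COLUMNS],
                      analysis_config()))
  # low-frequency sites sit above the cutoff and must not be rare
  low <- fdb[fdb$site_type == "low", raveburden:::VARIANT_COLUMNS]
  expect_false(any(is_rare(low, analysis_config())))
  # dbSNP-no-frequency sites split across the 1000 Genomes rule
  dbo <- fdb[fdb$site_type == "dbsnp_only", raveburden:::VARIANT_COLUMNS]
  r <- is_rare(dbo, analysis_config())
  expect_true(any(r) && !all(r))
  # 1000-Genomes-only sites are neither novel nor rare
  kgo <- fdb[fdb$site_type == "kg_only", raveburden:::VARIANT_COLUMNS]
  expect_false(any(is_novel(kgo)))
  expect_false(any(is_rare(kgo, analysis_config())))
})

test_that("common variants follow Hardy-Weinberg equilibrium", {
  st <- simulate_study(sim_config(missing_rate = 0), seed = 21)
  common <- which(st$cohort$variants$esp_freq > 0.04 &
                    !is.na(st$cohort$variants$esp_freq) &
                    is.na(match(st$cohort$variants$dbsnp_id,
                                c("rs429358", "rs7412"))))
  n <- nrow(st$cohort$samples)
  ok <- vapply(common, function(j) {
    q <- st$cohort$variants$esp_freq[j]
    expct <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    obs <- tabulate(st$cohort$genotypes[, j] + 1L, 3) / n
    se <- sqrt(expct * (1 - expct) / n)
    all(abs(obs - expct) <= 4 * se + 1e-9)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("a null planted odds ratio leaves carrier rates equal", {
  cfg <- sim_config(n_genes = 12, burden_or = 1)
  pan <- simulate_panel(cfg, 3)
  fdb <- simulate_freqdb(pan, cfg, 3)
  acfg <- analysis_config()
  diffs <- vapply(1:20, function(i) {
    co <- simulate_cohort(pan, fdb, cfg, seed = 300 + i)
    cl <- classify_variants(co, acfg)
    b <- burden_test(cl$cohort, cl$classification, pan, acfg)
    b$case_carriers / b$n_cases - b$control_carriers / b$n_controls
  }, 0)
  p <- cfg$control_carrier_prob
  se <- sqrt(p * (1 - p) * (1 / 242 + 1 / 129) / 20)
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("the shared-variant switch forces an excluded_shared call", {
  cfg <- sim_config(n_genes = 8, force_shared_variant = TRUE)
  st <- simulate_study(cfg, seed = 6)
  cl <- classify_variants(st$cohort)
  expect_gte(sum(cl$classification$status == "excluded_shared"), 1)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(control_carrier_prob = 1.2), "probability")
  expect_error(sim_config(burden_or = -2), "positive")
  expect_error(sim_config(apoe_freqs = c(e2 = 0.5, e3 = 0.2, e4 = 0.1)),
               "sum to 1")
  expect_error(sim_config(missing_rate = 2), "out of range")
})

test_that("quality failures appear at the configured fraction", {
  cfg <- sim_config(quality_fail_frac = 0.1)
  st <- simulate_study(cfg, seed = 17)
  qf <- apply_quality_filters(st$cohort$site_quality, analysis_config())
  k <- nrow(st$cohort$variants)
  expect_equal(sum(!qf$pass) / k, 0.1, tolerance = 0.05)
})
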