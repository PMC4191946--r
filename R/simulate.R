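## Synthetic case-control cohort generator. Produces a gene panel, a
## population-frequency site catalog and a genotyped cohort with the
## statistical structure the analysis assumes: common variants under
## Hardy-Weinberg equilibrium identically in both groups, private novel
## variants, a planted deleterious-carrier odds ratio in the
## known+associated gene set, a planted carrier-frequency effect in the
## stress-granule sub-set, an anchor pathogenic variant at the rarity
## cutoff, a two-SNP APOE locus with planted phenotype effects, and
## site-quality fields with a configured hard-filter failure fraction.

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# case probability implied by a control probability and an odds ratio
odds_scale <- function(p0, or) {
  if (p0 < 0 || p0 >= 1) stop("baseline probability must lie in [0, 1)")
  if (or <= 0) stop("odds ratio must be positive")
  o <- or * p0 / (1 - p0)
  o / (1 + o)
}

#' Simulation configuration
#'
#' Defaults mirror the study design: 242 cases and 129 controls over a
#' 169-gene panel split 22 known-ALS / 80 associated / 34 trios / 33 RRM,
#' an anchor pathogenic variant at ESP6500 frequency exactly 0.000538
#' carried by two cases, a planted deleterious-carrier odds ratio of 1.93
#' over the known+associated set, a stress-granule carrier odds ratio of
#' 5.5 (the value implied by 10/242 vs 1/129 carriers), and APOE
#' e2/e3/e4 allele frequencies 0.08/0.78/0.14 with planted
#' e2-vs-upper-limb-onset odds ratio 5.22 and e4-vs-female-within-limb
#' odds ratio 4.13.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_genes panel size; category counts scale proportionally.
#' @param n_common_per_gene,n_rare_per_gene,n_low_per_gene,n_dbsnp_only_per_gene,n_kg_only_per_gene
#'   database sites simulated per gene: common (HWE, both groups), rare
#'   (ESP at or below the cutoff), low-frequency (ESP just above the
#'   cutoff, must not classify rare), dbSNP-listed without frequency, and
#'   1000-Genomes-only.
#' @param benign_novel_rate expected private benign novel variants per
#'   sample (equal in both groups).
#' @param control_carrier_prob probability that a control is a
#'   deleterious-variant carrier in the target gene set.
#' @param burden_or planted case/control odds ratio for deleterious
#'   carriers.
#' @param sg_control_carrier_prob,sg_or stress-granule carrier probability
#'   in controls and planted carrier odds ratio.
#' @param apoe_freqs named numeric, e2/e3/e4 allele frequencies (sum 1).
#' @param e2_upper_limb_or,e4_female_limb_or planted APOE phenotype odds
#'   ratios.
#' @param onset_base baseline case onset-site probabilities
#'   (bulbar/upper_limb/limb).
#' @param n_female_cases,n_female_controls sex composition.
#' @param long_survivor_frac fraction of cases on the seven-year-survival
#'   panel.
#' @param anchor_freq,anchor_case_carriers anchor-variant ESP frequency
#'   and its number of case carriers.
#' @param quality_fail_frac fraction of sites violating one hard filter.
#' @param missing_rate per-genotype missingness.
#' @param force_shared_variant plant one novel variant carried by a case
#'   and a control, to exercise the shared-variant exclusion.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_cases = 242L, n_controls = 129L, n_genes = 169L,
                       n_common_per_gene = 2L, n_rare_per_gene = 2L,
                       n_low_per_gene = 1L, n_dbsnp_only_per_gene = 1L,
                       n_kg_only_per_gene = 1L,
                       benign_novel_rate = 0.5,
                       control_carrier_prob = 0.15,
                       burden_or = 1.93,
                       sg_control_carrier_prob = 1 / 129,
                       sg_or = 5.5,
                       apoe_freqs = c(e2 = 0.08, e3 = 0.78, e4 = 0.14),
                       e2_upper_limb_or = 5.22,
                       e4_female_limb_or = 4.13,
                       onset_base = c(bulbar = 0.33, upper_limb = 0.33,
                                      limb = 0.34),
                       n_female_cases = NULL, n_female_controls = NULL,
                       long_survivor_frac = 1 / 3,
                       anchor_freq = 0.000538, anchor_case_carriers = 2L,
                       quality_fail_frac = 0.02, missing_rate = 0.01,
                       force_shared_variant = FALSE) {
  if (is.null(n_female_cases))
    n_female_cases <- round(111 / 242 * n_cases)
  if (is.null(n_female_controls))
    n_female_controls <- round(69 / 129 * n_controls)
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_genes = as.integer(n_genes),
              n_common_per_gene = n_common_per_gene,
              n_rare_per_gene = n_rare_per_gene,
              n_low_per_gene = n_low_per_gene,
              n_dbsnp_only_per_gene = n_dbsnp_only_per_gene,
              n_kg_only_per_gene = n_kg_only_per_gene,
              benign_novel_rate = benign_novel_rate,
              control_carrier_prob = control_carrier_prob,
              burden_or = burden_or,
              sg_control_carrier_prob = sg_control_carrier_prob,
              sg_or = sg_or,
              apoe_freqs = apoe_freqs,
              e2_upper_limb_or = e2_upper_limb_or,
              e4_female_limb_or = e4_female_limb_or,
              onset_base = onset_base,
              n_female_cases = as.integer(n_female_cases),
              n_female_controls = as.integer(n_female_controls),
              long_survivor_frac = long_survivor_frac,
              anchor_freq = anchor_freq,
              anchor_case_carriers = as.integer(anchor_case_carriers),
              quality_fail_frac = quality_fail_frac,
              missing_rate = missing_rate,
              force_shared_variant = isTRUE(force_shared_variant))
  if (cfg$n_cases <= 0 || cfg$n_controls <= 0 || cfg$n_genes <= 0)
    stop("cohort and panel sizes must be positive")
  if (abs(sum(cfg$apoe_freqs) - 1) > 1e-8)
    stop("APOE allele frequencies must sum to 1")
  if (any(cfg$apoe_freqs < 0))
    stop("APOE allele frequencies must be non-negative")
  for (nm in c("benign_novel_rate", "quality_fail_frac", "missing_rate",
               "long_survivor_frac"))
    if (cfg[[nm]] < 0 || (nm != "benign_novel_rate" && cfg[[nm]] > 1))
      stop("'", nm, "' out of range")
  # these raise config errors for infeasible probability/odds combinations
  odds_scale(cfg$control_carrier_prob, cfg$burden_or)
  odds_scale(cfg$sg_control_carrier_prob, cfg$sg_or)
  structure(cfg, class = "sim_config")
}

#' Simulate a gene panel
#'
#' Category counts scale from the 22/80/34/33 design proportions; a few
#' known genes also carry the rrm category (genes may belong to several
#' categories). The APOE gene is always present (associated category).
#' Sub-set tags: stress_granule (on known and rrm genes), hnrnp (rrm) and
#' chromatin (trios).
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return validated panel data frame.
#' @export
simulate_panel <- function(config = sim_config(), seed = 1) {
  with_seed(seed, {
    ng <- config$n_genes
    props <- c(known_als = 22, associated = 80, trios = 34, rrm = 33) / 169
    counts <- stats::setNames(pmax(1L, round(props * ng)), names(props))
    counts["associated"] <- ng - sum(counts[c("known_als", "trios", "rrm")])
    if (counts["associated"] < 1)
      stop("panel too small for the four categories")
    cats <- rep(names(counts), counts)
    gene <- sprintf("GENE%03d", seq_len(ng))
    # APOE is an associated-category gene
    gene[which(cats == "associated")[1]] <- "APOE"
    categories <- cats
    # overlap: some known genes also contain an RRM (FUS-like)
    n_overlap <- min(3L, counts["known_als"])
    ov <- which(cats == "known_als")[seq_len(n_overlap)]
    categories[ov] <- "known_als,rrm"

    subsets <- rep("", ng)
    sg_pool <- which(cats %in% c("known_als", "rrm"))
    n_sg <- max(2L, round(15 / 169 * ng))
    sg <- sg_pool[seq_len(min(n_sg, length(sg_pool)))]
    subsets[sg] <- "stress_granule"
    rrm_only <- setdiff(which(cats == "rrm"), sg)
    hn <- rrm_only[seq_len(min(max(1L, round(8 / 169 * ng)),
                               length(rrm_only)))]
    subsets[hn] <- paste0(subsets[hn], ifelse(subsets[hn] == "", "", ","),
                          "hnrnp")
    tr <- which(cats == "trios")[seq_len(min(max(1L, round(5 / 169 * ng)),
                                             counts["trios"]))]
    subsets[tr] <- paste0(subsets[tr], ifelse(subsets[tr] == "", "", ","),
                          "chromatin")
    validate_panel(data.frame(gene = gene, categories = categories,
                              subsets = subsets,
                              rvis = round(stats::rnorm(ng), 3),
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a population-frequency site catalog
#'
#' Per gene: common sites (ESP and 1000G frequencies 0.05-0.5), rare
#' sites (ESP uniform below the rarity cutoff), a low-frequency site just
#' above the cutoff (exercising the inclusive boundary), a dbSNP-listed
#' site without any frequency (1000G below or above 0.01 to exercise that
#' rule), and a 1000-Genomes-only site. The first known-ALS gene carries
#' the anchor pathogenic variant at ESP frequency exactly
#' \code{anchor_freq}. The APOE gene carries the two epsilon-defining
#' SNPs (rs429358, rs7412) at the configured allele frequencies.
#'
#' @param panel validated panel data frame.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return data frame of annotated database sites (one row per site).
#' @export
simulate_freqdb <- function(panel, config = sim_config(), seed = 1) {
  panel <- validate_panel(panel)
  with_seed(seed + 1L, {
    genes <- panel$gene
    gi <- seq_along(genes)
    types <- c(common = config$n_common_per_gene,
               rare = config$n_rare_per_gene,
               low = config$n_low_per_gene,
               dbsnp_only = config$n_dbsnp_only_per_gene,
               kg_only = config$n_kg_only_per_gene)
    gene_v <- character(0); type_v <- character(0)
    for (ty in names(types)) {
      gene_v <- c(gene_v, rep(genes, each = types[[ty]]))
      type_v <- c(type_v, rep(ty, length(genes) * types[[ty]]))
    }
    k <- length(gene_v)
    cut <- config$anchor_freq
    esp <- rep(NA_real_, k); kg <- rep(NA_real_, k)
    in_db <- rep(TRUE, k); has_fr <- rep(TRUE, k)
    is_common <- type_v == "common"
    esp[is_common] <- stats::runif(sum(is_common), 0.05, 0.5)
    kg[is_common] <- esp[is_common]
    is_rare <- type_v == "rare"
    esp[is_rare] <- stats::runif(sum(is_rare), cut / 10, cut)
    is_low <- type_v == "low"
    esp[is_low] <- stats::runif(sum(is_low), cut * 1.1, 0.005)
    is_do <- type_v == "dbsnp_only"
    has_fr[is_do] <- FALSE
    # alternate: no 1000G entry / below 0.01 (rare) / at or above (not rare)
    do_idx <- which(is_do)
    kg[do_idx[seq_along(do_idx) %% 3 == 1]] <- stats::runif(
      sum(seq_along(do_idx) %% 3 == 1), 0.001, 0.009)
    kg[do_idx[seq_along(do_idx) %% 3 == 2]] <- stats::runif(
      sum(seq_along(do_idx) %% 3 == 2), 0.011, 0.05)
    is_kg <- type_v == "kg_only"
    in_db[is_kg] <- FALSE; has_fr[is_kg] <- FALSE
    kg[is_kg] <- stats::runif(sum(is_kg), 0.02, 0.3)

    func <- rep("nonsynonymous", k)
    func[is_common] <- rep_len(c("synonymous", "nonsynonymous"),
                               sum(is_common))
    pp <- rep(NA_real_, k)
    scored <- func == "nonsynonymous"
    # database variants segregating in healthy populations lean benign;
    # kept below the damaging threshold so planted carrier processes stay
    # exactly calibrated
    pp[scored & !is_common] <- stats::runif(sum(scored & !is_common), 0, 0.84)
    pp[scored & is_common] <- stats::runif(sum(scored & is_common), 0, 1)

    df <- data.frame(
      chrom = paste0("chr", (match(gene_v, genes) - 1L) %% 22L + 1L),
      pos = 0L, ref = "A", alt = "G",
      gene = gene_v,
      protein_change = NA_character_,
      functional_class = func,
      in_dbsnp = in_db,
      dbsnp_id = NA_character_,
      dbsnp_has_freq = has_fr & in_db,
      esp_freq = esp, kg_freq = kg,
      polyphen_score = pp,
      polyphen_label = NA_character_,
      sift_label = NA_character_,
      mutationtaster_label = NA_character_,
      phylop_label = NA_character_,
      site_type = type_v,
      stringsAsFactors = FALSE)

    # anchor pathogenic variant in the first known-ALS gene
    anchor_gene <- panel_genes(panel, "known_als")[1]
    anchor <- df[1, ]
    anchor$gene <- anchor_gene
    anchor$functional_class <- "nonsynonymous"
    anchor$in_dbsnp <- TRUE; anchor$dbsnp_has_freq <- TRUE
    anchor$esp_freq <- config$anchor_freq; anchor$kg_freq <- NA_real_
    anchor$polyphen_score <- 0.99; anchor$polyphen_label <- "D"
    anchor$protein_change <- "p.D91A"
    anchor$site_type <- "anchor"
    # APOE epsilon-defining SNPs
    a130 <- df[1, ]
    a130$gene <- "APOE"; a130$functional_class <- "nonsynonymous"
    a130$in_dbsnp <- TRUE; a130$dbsnp_has_freq <- TRUE
    a130$dbsnp_id <- "rs429358"
    a130$esp_freq <- unname(config$apoe_freqs["e4"])
    a130$kg_freq <- a130$esp_freq
    a130$polyphen_score <- NA_real_
    a130$protein_change <- "p.C130R"
    a130$site_type <- "apoe_130"
    a176 <- a130
    a176$dbsnp_id <- "rs7412"
    a176$esp_freq <- unname(config$apoe_freqs["e2"])
    a176$kg_freq <- a176$esp_freq
    a176$protein_change <- "p.R176C"
    a176$site_type <- "apoe_176"

    df <- rbind(df, anchor, a130, a176)
    df$pos <- seq_len(nrow(df)) * 101L
    df$dbsnp_id <- ifelse(df$in_dbsnp & is.na(df$dbsnp_id),
                          paste0("rs", 10000L + seq_len(nrow(df))),
                          df$dbsnp_id)
    refalt <- matrix(c("A", "G", "C", "T", "G", "C", "T", "A"), ncol = 2)
    pick <- (seq_len(nrow(df)) - 1L) %% 4L + 1L
    df$ref <- refalt[pick, 1]; df$alt <- refalt[pick, 2]
    rownames(df) <- NULL
    df
  })
}

# multiply the odds of outcome `idx` of probability vector p by `or`,
# renormalizing the remaining mass
.adjust_onset <- function(p, idx, or) {
  o <- or * p[idx] / (1 - p[idx])
  pn <- o / (1 + o)
  rest <- p[-idx] / sum(p[-idx]) * (1 - pn)
  out <- numeric(length(p))
  out[idx] <- pn; out[-idx] <- rest
  names(out) <- names(p)
  out
}

#' Simulate a genotyped case-control cohort
#'
#' See \code{\link{sim_config}} for the generative model. Common database
#' sites are drawn under Hardy-Weinberg equilibrium from their catalog
#' frequencies, identically in both groups; rarer database sites are
#' drawn binomially at their catalog frequency; each planted novel
#' variant is private to one individual. Deleterious-carrier status
#' (one private novel variant scoring at or above 0.85 in the
#' known+associated set) is Bernoulli per sample with the planted odds
#' ratio between groups; stress-granule carriage is planted analogously
#' but with sub-threshold scores so the two planted effects stay
#' independent. APOE genotypes come from per-sample allele pairs, which
#' also drive the planted onset-site and sex effects.
#'
#' @param panel validated panel data frame.
#' @param freqdb value of \code{\link{simulate_freqdb}} on it.
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed.
#' @return a \code{\link{cohort_data}}.
#' @export
simulate_cohort <- function(panel, freqdb, config = sim_config(), seed = 1) {
  panel <- validate_panel(panel)
  with_seed(seed + 2L, {
    n_ca <- config$n_cases; n_co <- config$n_controls
    n <- n_ca + n_co
    is_case <- c(rep(TRUE, n_ca), rep(FALSE, n_co))
    ids <- c(sprintf("CASE%04d", seq_len(n_ca)),
             sprintf("CTRL%04d", seq_len(n_co)))
    sex <- c(rep(c("female", "male"),
                 c(config$n_female_cases, n_ca - config$n_female_cases)),
             rep(c("female", "male"),
                 c(config$n_female_controls, n_co - config$n_female_controls)))

    ## APOE allele pairs and planted phenotype structure
    al <- matrix(sample(names(config$apoe_freqs), 2L * n, replace = TRUE,
                        prob = config$apoe_freqs), ncol = 2)
    d130 <- rowSums(al == "e4")
    d176 <- rowSums(al == "e2")
    e2_carrier <- d176 >= 1
    e4_carrier <- d130 >= 1

    onset <- rep("unknown", n)
    for (i in seq_len(n_ca)) {
      p <- config$onset_base
      if (e2_carrier[i])
        p <- .adjust_onset(p, which(names(p) == "upper_limb"),
                           config$e2_upper_limb_or)
      if (e4_carrier[i] && sex[i] == "female")
        p <- .adjust_onset(p, which(names(p) == "limb"),
                           config$e4_female_limb_or)
      onset[i] <- sample(names(p), 1, prob = p)
    }
    age <- rep(NA_real_, n)
    age[is_case] <- round(pmin(82, pmax(44, stats::rnorm(n_ca, 60, 8))))
    long_surv <- c(seq_len(n_ca) <= round(config$long_survivor_frac * n_ca),
                   rep(FALSE, n_co))
    manifest <- data.frame(sample_id = ids,
                           group = ifelse(is_case, "case", "control"),
                           sex = sex, onset_site = onset,
                           age_of_onset = age, long_survivor = long_surv,
                           stringsAsFactors = FALSE)

    ## database-site genotypes
    db <- freqdb
    k_db <- nrow(db)
    freq <- ifelse(!is.na(db$esp_freq), db$esp_freq,
                   ifelse(!is.na(db$kg_freq), db$kg_freq, 0.0005))
    geno_db <- matrix(stats::rbinom(n * k_db, 2L, rep(freq, each = n)),
                      nrow = n)
    apoe_cols <- match(c("apoe_130", "apoe_176"), db$site_type)
    geno_db[, apoe_cols[1]] <- d130
    geno_db[, apoe_cols[2]] <- d176
    anchor_col <- match("anchor", db$site_type)
    geno_db[, anchor_col] <- 0L

    ## planted carrier processes
    p_burden <- ifelse(is_case,
                       odds_scale(config$control_carrier_prob,
                                  config$burden_or),
                       config$control_carrier_prob)
    del_carrier <- stats::runif(n) < p_burden
    p_sg <- ifelse(is_case,
                   odds_scale(config$sg_control_carrier_prob, config$sg_or),
                   config$sg_control_carrier_prob)
    sg_carrier <- stats::runif(n) < p_sg

    target_genes <- panel_genes(panel, c("known_als", "associated"))
    sg_genes <- panel_subset_genes(panel, "stress_granule")
    if (length(sg_genes) == 0) sg_carrier[] <- FALSE

    # the anchor's carriers are deleterious carriers (known pathogenic);
    # assign it to planted case carriers when possible
    anchor_pool <- which(del_carrier & is_case)
    if (length(anchor_pool) < config$anchor_case_carriers)
      anchor_pool <- which(is_case)
    anchor_carriers <- anchor_pool[seq_len(min(config$anchor_case_carriers,
                                               length(anchor_pool)))]
    geno_db[anchor_carriers, anchor_col] <- 1L

    ## private novel variants
    novel_sample <- integer(0); novel_gene <- character(0)
    novel_score <- numeric(0); novel_class <- character(0)
    n_benign <- stats::rpois(n, config$benign_novel_rate)
    if (sum(n_benign) > 0) {
      smp <- rep(seq_len(n), n_benign)
      novel_sample <- c(novel_sample, smp)
      novel_gene <- c(novel_gene,
                      sample(panel$gene, length(smp), replace = TRUE))
      novel_score <- c(novel_score, stats::runif(length(smp), 0, 0.84))
      novel_class <- c(novel_class, rep("nonsynonymous", length(smp)))
    }
    del_idx <- which(del_carrier)
    if (length(del_idx)) {
      novel_sample <- c(novel_sample, del_idx)
      novel_gene <- c(novel_gene,
                      sample(target_genes, length(del_idx), replace = TRUE))
      cls <- sample(c("nonsynonymous", "stopgain", "frameshift"),
                    length(del_idx), replace = TRUE,
                    prob = c(0.85, 0.1, 0.05))
      # PolyPhen does not score truncating variants; the damaging-score
      # policy handles them downstream
      sc <- stats::runif(length(del_idx), 0.85, 1)
      sc[cls != "nonsynonymous"] <- NA_real_
      novel_score <- c(novel_score, sc)
      novel_class <- c(novel_class, cls)
    }
    sg_idx <- which(sg_carrier)
    if (length(sg_idx)) {
      novel_sample <- c(novel_sample, sg_idx)
      novel_gene <- c(novel_gene,
                      sample(sg_genes, length(sg_idx), replace = TRUE))
      novel_score <- c(novel_score, stats::runif(length(sg_idx), 0, 0.84))
      novel_class <- c(novel_class, rep("nonsynonymous", length(sg_idx)))
    }
    k_novel <- length(novel_sample)
    geno_novel <- matrix(0L, n, k_novel)
    if (k_novel)
      geno_novel[cbind(novel_sample, seq_len(k_novel))] <- 1L

    if (config$force_shared_variant) {
      shared <- integer(n)
      shared[c(1L, n_ca + 1L)] <- 1L        # one case and one control
      geno_novel <- cbind(geno_novel, shared)
      novel_gene <- c(novel_gene, panel$gene[1])
      novel_score <- c(novel_score, 0.5)
      novel_class <- c(novel_class, "nonsynonymous")
      k_novel <- k_novel + 1L
    }

    novel_df <- data.frame(
      chrom = paste0("chr", (match(novel_gene, panel$gene) - 1L) %% 22L + 1L),
      pos = max(db$pos) + seq_len(k_novel) * 101L,
      ref = "C", alt = "T",
      gene = novel_gene,
      protein_change = sprintf("p.N%dS", seq_len(k_novel)),
      functional_class = novel_class,
      in_dbsnp = FALSE, dbsnp_id = NA_character_, dbsnp_has_freq = FALSE,
      esp_freq = NA_real_, kg_freq = NA_real_,
      polyphen_score = novel_score,
      polyphen_label = ifelse(is.na(novel_score), NA_character_,
                              ifelse(novel_score >= 0.85, "D",
                                     ifelse(novel_score >= 0.5, "P", "B"))),
      sift_label = NA_character_, mutationtaster_label = NA_character_,
      phylop_label = NA_character_,
      stringsAsFactors = FALSE)
    if (k_novel == 0) novel_df <- novel_df[0, ]

    variants <- rbind(db[, VARIANT_COLUMNS], novel_df[, VARIANT_COLUMNS])
    geno <- cbind(geno_db, geno_novel)
    k <- ncol(geno)

    ## site quality: passing values, with a configured failing fraction
    q <- data.frame(
      dp = stats::rpois(k, 55) + 5,
      qual = stats::runif(k, 60, 2000),
      qd = stats::runif(k, 5, 30),
      fs = stats::runif(k, 0, 20),
      haplotype_score = stats::runif(k, 0, 10),
      mq = stats::runif(k, 40, 60),
      mq_rank_sum = stats::rnorm(k, 0, 2),
      read_pos_rank_sum = stats::rnorm(k, 0, 2))
    n_fail <- round(config$quality_fail_frac * k)
    if (n_fail > 0) {
      fail_sites <- sample.int(k, n_fail)
      rule <- sample(8L, n_fail, replace = TRUE)
      bad_vals <- list(function(m) 0, function(m) 10, function(m) 1,
                       function(m) 80, function(m) 20, function(m) 15,
                       function(m) -20, function(m) -12)
      for (j in seq_len(n_fail))
        q[fail_sites[j], rule[j]] <- bad_vals[[rule[j]]](1)
    }

    if (config$missing_rate > 0) {
      miss <- stats::runif(n * k) < config$missing_rate
      geno[miss] <- NA_integer_
    }

    cohort_data(manifest, variants, geno, q)
  })
}

#' Simulate a complete study (panel, site catalog, cohort)
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed integer seed driving all three stages.
#' @param dir if non-NULL, write the study inputs there via
#'   \code{\link{write_study}}.
#' @return list with \code{panel}, \code{freqdb}, \code{cohort} and, when
#'   written, \code{files}.
#' @export
simulate_study <- function(config = sim_config(), seed = 1, dir = NULL) {
  panel <- simulate_panel(config, seed)
  freqdb <- simulate_freqdb(panel, config, seed)
  cohort <- simulate_cohort(panel, freqdb, config, seed)
  out <- list(panel = panel, freqdb = freqdb, cohort = cohort)
  if (!is.null(dir)) out$files <- write_study(out, dir)
  out
}

#' Write simulated study inputs to a directory
#'
#' Emits cohort.vcf, annotations.tsv, manifest.tsv, panel.tsv and
#' freqdb.tsv, the input set consumed by \code{\link{run_pipeline}}.
#'
#' @param study value of \code{\link{simulate_study}}.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             manifest = file.path(dir, "manifest.tsv"),
             panel = file.path(dir, "panel.tsv"),
             freqdb = file.path(dir, "freqdb.tsv"))
  write_vcf(study$cohort, paths["vcf"])
  write_tsv(study$cohort$variants, paths["annotations"])
  write_tsv(study$cohort$samples, paths["manifest"])
  write_tsv(study$panel, paths["panel"])
  fdb_cols <- c("chrom", "pos", "ref", "alt", "gene", "in_dbsnp",
                "dbsnp_id", "dbsnp_has_freq", "esp_freq", "kg_freq")
  write_tsv(study$freqdb[fdb_cols], paths["freqdb"])
  paths
}
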