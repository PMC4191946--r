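## End-to-end orchestration: read inputs, filter, classify, test, report.

fmt_fisher_row <- function(label, fr, extra = list()) {
  row <- data.frame(test = label, stringsAsFactors = FALSE)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row$p <- fr$p_two_sided
  row$or_cmle <- fr$or_cmle
  row$ci_low <- fr$ci_low
  row$ci_high <- fr$ci_high
  row$method <- fr$method
  row$degenerate <- fr$degenerate
  row
}

#' Run the full analysis pipeline
#'
#' Stages: input reading and cross-validation, site quality filtering,
#' functional restriction, novel/rare classification with the shared
#' case/control exclusion, the PolyPhen-weighted burden test over the
#' known+associated gene set, per-gene and total prevalence, common-SNP
#' carrier tests, sub-set (e.g. stress-granule) enrichment, and the APOE
#' epsilon-diplotype battery. All result tables are written as TSV;
#' identical inputs yield byte-identical outputs.
#'
#' @param config either a list or a YAML/JSON file path with elements
#'   \code{inputs} (paths: vcf, annotations, manifest, panel) and
#'   optionally \code{analysis} (overrides for
#'   \code{\link{analysis_config}} fields).
#' @param output_dir directory for result tables (created if needed).
#' @return object of class \code{run_report}: configuration echo,
#'   per-stage record counts, all test results and the output inventory.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$inputs))
    stop("pipeline config needs an 'inputs' element")
  req <- c("vcf", "annotations", "manifest", "panel")
  miss <- setdiff(req, names(config$inputs))
  if (length(miss))
    stop("pipeline config lacks input path(s): ",
         paste(miss, collapse = ", "))
  for (p in unlist(config$inputs[req]))
    if (!file.exists(p)) stop("input file does not exist: ", p)

  acfg <- do.call(analysis_config,
                  if (is.null(config$analysis)) list() else config$analysis)

  message("stage: input")
  vcf <- read_vcf(config$inputs$vcf)
  annotations <- read_annotations(config$inputs$annotations)
  manifest <- read_manifest(config$inputs$manifest)
  panel <- read_panel(config$inputs$panel)
  cohort <- assemble_cohort(vcf, annotations, manifest)
  acfg$n_cases <- sum(cohort$samples$group == "case")
  acfg$n_controls <- sum(cohort$samples$group == "control")

  message("stage: classification")
  cl <- classify_variants(cohort, acfg)
  cls <- cl$classification

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(cls, file.path(output_dir, "classification.tsv"))

  message("stage: burden")
  burden <- burden_test(cl$cohort, cls, panel, acfg)
  write_tsv(fmt_fisher_row("burden_known_associated", burden$fisher,
                           list(case_carriers = burden$case_carriers,
                                control_carriers = burden$control_carriers)),
            file.path(output_dir, "burden_summary.tsv"))
  write_tsv(data.frame(sample_id = names(burden$scores),
                       score = unname(burden$scores)),
            file.path(output_dir, "burden_scores.tsv"))

  message("stage: prevalence")
  prev_genes <- sort(unique(cls$gene[is_qualifying(cls)]))
  prev <- do.call(rbind, c(
    lapply(prev_genes, function(g)
      gene_prevalence(cls, g, "cases", acfg$n_cases)),
    list(prevalence_total(cls, prev_genes, "cases", acfg$n_cases))))
  prev_ctrl <- do.call(rbind, c(
    lapply(prev_genes, function(g)
      gene_prevalence(cls, g, "controls", acfg$n_controls)),
    list(prevalence_total(cls, prev_genes, "controls", acfg$n_controls))))
  prev$group <- "cases"; prev_ctrl$group <- "controls"
  write_tsv(rbind(prev, prev_ctrl),
            file.path(output_dir, "prevalence.tsv"))

  message("stage: snp association")
  snp_idx <- which(cls$status == "common" & !is.na(cls$dbsnp_id))
  snp_rows <- lapply(snp_idx, function(i) {
    fr <- snp_carrier_test(cls$case_carriers[i], cls$control_carriers[i],
                           acfg$n_cases, acfg$n_controls,
                           method = acfg$test_method)
    fmt_fisher_row(cls$dbsnp_id[i], fr,
                   list(gene = cls$gene[i],
                        case_carriers = cls$case_carriers[i],
                        control_carriers = cls$control_carriers[i]))
  })
  snp_tab <- if (length(snp_rows)) do.call(rbind, snp_rows) else NULL
  if (!is.null(snp_tab))
    write_tsv(snp_tab, file.path(output_dir, "snp_tests.tsv"))

  message("stage: category enrichment")
  tags <- sort(setdiff(unique(unlist(
    strsplit(panel$subsets, ",", fixed = TRUE))), ""))
  enrich <- lapply(tags, function(tg)
    category_enrichment(cls, panel, tg, acfg))
  names(enrich) <- tags
  if (length(enrich)) {
    write_tsv(do.call(rbind, lapply(enrich, function(e)
      fmt_fisher_row(e$tag, e$fisher,
                     list(case_carriers = e$case_carriers,
                          control_carriers = e$control_carriers,
                          case_pct = e$case_pct,
                          control_pct = e$control_pct)))),
      file.path(output_dir, "category_enrichment.tsv"))
  }

  message("stage: apoe")
  apoe_res <- NULL
  i130 <- match("rs429358", cohort$variants$dbsnp_id)
  i176 <- match("rs7412", cohort$variants$dbsnp_id)
  if (!is.na(i130) && !is.na(i176)) {
    diplo <- call_apoe(cohort$genotypes[, i130], cohort$genotypes[, i176],
                       cohort$samples$sample_id)
    write_tsv(diplo, file.path(output_dir, "apoe_diplotypes.tsv"))
    apoe_res <- apoe_strata_tests(diplo, cohort$samples,
                                  method = acfg$test_method)
    fr_names <- setdiff(names(apoe_res), "age_of_onset_medians")
    write_tsv(do.call(rbind, lapply(fr_names, function(nm)
      fmt_fisher_row(nm, apoe_res[[nm]]$fisher))),
      file.path(output_dir, "apoe_tests.tsv"))
  }

  counts <- cl$counts
  report <- structure(list(
    config = list(inputs = config$inputs, analysis = unclass(acfg)),
    input_digests = vapply(unlist(config$inputs[req]),
                           function(p) unname(tools::md5sum(p)), ""),
    stage_counts = as.list(counts),
    burden = burden,
    enrichment = enrich,
    apoe = apoe_res,
    outputs = list.files(output_dir)),
    class = "run_report")
  report_json <- list(stage_counts = as.list(counts),
                      burden = list(case_carriers = burden$case_carriers,
                                    control_carriers = burden$control_carriers,
                                    p = burden$fisher$p_two_sided,
                                    or = burden$fisher$or_cmle),
                      outputs = report$outputs)
  writeLines(jsonlite::toJSON(report_json, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(output_dir, "report.json"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  cat("stage counts:\n")
  print(unlist(x$stage_counts))
  cat("burden test:\n")
  print(x$burden)
  invisible(x)
}
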