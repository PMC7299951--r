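# File I/O, configuration and orchestration of the full analysis.

#' Pipeline configuration
#'
#' @param sample_sheet,ct_m0,ct_mf,methylation,cpg_map input file paths;
#'   `methylation`/`cpg_map` may be `NULL` to skip that section.
#' @param reference_gene housekeeping gene for delta-Ct normalization.
#' @param calibrator calibrator strategy for [relative_expression()].
#' @param analysis_scale scale on which baseline values are z-scored and
#'   longitudinal change is computed: `"log2rq"` (default; Livak relative
#'   quantities are log-normally distributed, so group testing is done on
#'   their log2) or `"rq"`.
#' @param B number of permutations per test (study convention 10000).
#' @param seed master seed; stage seeds are derived deterministically.
#' @param n_components leading principal components tested.
#' @param fdr_threshold significance threshold applied to FDR-adjusted
#'   permutation p-values in reports.
#' @param smooth_p use the (k+1)/(B+1) permutation-p estimator.
#' @param case_group,reference_group outcome and standardization group
#'   labels.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sample_sheet, ct_m0, ct_mf,
                            methylation = NULL, cpg_map = NULL,
                            reference_gene = "GAPDH",
                            calibrator = "reference_group_mean",
                            analysis_scale = c("log2rq", "rq"),
                            B = 10000L, seed = 1L, n_components = 3L,
                            fdr_threshold = 0.05, smooth_p = FALSE,
                            case_group = "converter",
                            reference_group = "non-converter") {
  analysis_scale <- match.arg(analysis_scale)
  if (B < 1L) stop_named("B must be >= 1")
  if (fdr_threshold <= 0 || fdr_threshold >= 1)
    stop_named("fdr_threshold must be in (0, 1)")
  structure(list(
    sample_sheet = sample_sheet, ct_m0 = ct_m0, ct_mf = ct_mf,
    methylation = methylation, cpg_map = cpg_map,
    reference_gene = reference_gene, calibrator = calibrator,
    analysis_scale = analysis_scale, B = as.integer(B),
    seed = as.integer(seed),
    n_components = as.integer(n_components),
    fdr_threshold = fdr_threshold, smooth_p = smooth_p,
    case_group = case_group, reference_group = reference_group
  ), class = "pipeline_config")
}

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop_named("%s file not found: %s", what, path)
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0)
    stop_named("%s (%s) is missing required column(s): %s",
               what, basename(path), paste(missing, collapse = ", "))
  if ("subject_id" %in% names(d) && anyDuplicated(d$subject_id))
    stop_named("%s has duplicated subject_id values", what)
  d
}

#' Read and validate the pipeline input files
#'
#' Reads the sample sheet, the two wide Ct tables and (optionally) the
#' methylation matrix and gene-CpG map, validating schemas and subject
#' consistency.  Hard errors name the offending file and column.
#'
#' @param config a [pipeline_config()].
#' @return list `cohort`, `ct_m0`, `ct_mf`, `methylation` (or `NULL`),
#'   `cpg_map` (or `NULL`), plus `log`: per-table row counts.
#' @export
read_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- read_checked_csv(config$sample_sheet,
                             c("subject_id", "group", "age", "sex", "cpz_eq"),
                             "sample sheet")
  bad <- setdiff(unique(cohort$group),
                 c(config$case_group, config$reference_group))
  if (length(bad) > 0)
    stop_named("sample sheet contains unknown group label(s): %s",
               paste(bad, collapse = ", "))
  if (any(!is.na(cohort$age) & cohort$age <= 0))
    stop_named("sample sheet has non-positive age values")
  if (any(!is.na(cohort$cpz_eq) & cohort$cpz_eq < 0))
    stop_named("sample sheet has negative cpz_eq values")
  ct_m0 <- read_checked_csv(config$ct_m0,
                            c("subject_id", config$reference_gene),
                            "baseline Ct table")
  ct_mf <- read_checked_csv(config$ct_mf,
                            c("subject_id", config$reference_gene),
                            "follow-up Ct table")
  orphan <- setdiff(c(ct_m0$subject_id, ct_mf$subject_id), cohort$subject_id)
  if (length(orphan) > 0)
    stop_named("Ct tables contain subject(s) absent from the sample sheet: %s",
               paste(utils::head(orphan, 5L), collapse = ", "))
  new_mf <- setdiff(ct_mf$subject_id, ct_m0$subject_id)
  if (length(new_mf) > 0)
    stop_named("follow-up subjects missing at baseline: %s",
               paste(utils::head(new_mf, 5L), collapse = ", "))
  meth <- map <- NULL
  if (!is.null(config$methylation)) {
    meth <- read_checked_csv(config$methylation, "subject_id", "methylation")
    map <- read_checked_csv(config$cpg_map,
                            c("cpg_id", "gene", "region"), "CpG map")
    if (!all(map$region %in% c("promoter", "body")))
      stop_named("CpG map regions must be 'promoter' or 'body'")
  }
  list(cohort = cohort, ct_m0 = ct_m0, ct_mf = ct_mf,
       methylation = meth, cpg_map = map,
       log = c(n_cohort = nrow(cohort), n_m0 = nrow(ct_m0),
               n_mf = nrow(ct_mf),
               n_meth = if (is.null(meth)) 0L else nrow(meth)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates, in order: demographics comparison, delta-Ct normalization
#' at both time points, Livak relative expression, reference-group
#' z-scoring, the baseline gene-panel test, longitudinal change and its
#' panel test, the gene-gene correlation matrix, PCA with component-level
#' group tests, Spearman correlations of baseline expression with end-of-
#' follow-up clinical scores, and (when provided) per-CpG methylation-
#' expression correlations.  Deterministic under `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with elements `demographics`,
#'   `baseline_panel`, `longitudinal_panel`, `correlations`, `pca`,
#'   `pc_panel`, `clinical`, `methylation` (or `NULL`) and `manifest`
#'   (configuration, seeds and subject accounting at every stage).
#' @export
run_full_pipeline <- function(config) {
  inputs <- read_inputs(config)
  cohort <- inputs$cohort
  groups <- stats::setNames(cohort$group, cohort$subject_id)

  demographics <- cohort_summary(cohort, case_group = config$case_group,
                                 reference_group = config$reference_group)

  dct_m0 <- delta_ct(inputs$ct_m0, config$reference_gene)
  dct_mf <- delta_ct(inputs$ct_mf, config$reference_gene)
  rq_m0 <- relative_expression(dct_m0, config$calibrator, groups = groups,
                               reference_group = config$reference_group)
  rq_mf <- relative_expression(dct_mf, config$calibrator, groups = groups,
                               reference_group = config$reference_group)
  use_log2 <- config$analysis_scale == "log2rq"
  base_in <- if (use_log2) log2_rq(rq_m0) else rq_m0
  z_m0 <- zscore_on_reference(base_in, groups, config$reference_group)

  baseline_panel <- gene_panel_test(
    z_m0, cohort, family = "baseline", B = config$B,
    seed = child_seed(config$seed, 1L), smooth = config$smooth_p,
    case_group = config$case_group)

  chg_in_m0 <- if (use_log2) log2_rq(rq_m0) else rq_m0
  chg_in_mf <- if (use_log2) log2_rq(rq_mf) else rq_mf
  change <- longitudinal_change(chg_in_m0, chg_in_mf)
  z_change <- zscore_on_reference(change, groups, config$reference_group)
  longitudinal_panel <- gene_panel_test(
    z_change, cohort, family = "longitudinal", B = config$B,
    seed = child_seed(config$seed, 2L), smooth = config$smooth_p,
    case_group = config$case_group)

  correlations <- correlation_matrix(z_m0)
  pca <- run_pca(z_m0, scale = TRUE)
  pc_panel <- pc_group_test(
    pca, cohort, n_components = config$n_components, B = config$B,
    seed = child_seed(config$seed, 3L), smooth = config$smooth_p,
    case_group = config$case_group)

  clin_cols <- intersect(c("bprs_mf", "cgi_mf", "panss_neg_mf", "caarms_mf"),
                         names(cohort))
  clinical <- NULL
  if (length(clin_cols) > 0) {
    sc <- cohort[, c("subject_id", clin_cols), drop = FALSE]
    clinical <- clinical_spearman(unclass(z_m0), sc)
  }

  methylation <- NULL
  if (!is.null(inputs$methylation)) {
    methylation <- methylation_expression_correlation(
      inputs$methylation, z_m0, inputs$cpg_map)
  }

  manifest <- list(
    config = unclass(config),
    seeds = c(baseline = child_seed(config$seed, 1L),
              longitudinal = child_seed(config$seed, 2L),
              pc = child_seed(config$seed, 3L)),
    n = c(inputs$log,
          n_baseline_used = nrow(z_m0),
          n_longitudinal_used = nrow(z_change),
          n_pca_used = pca$n_used),
    dropped = c(
      baseline = as.integer(inputs$log[["n_cohort"]] - nrow(z_m0)),
      longitudinal = as.integer(inputs$log[["n_m0"]] - nrow(z_change))),
    package_version = as.character(utils::packageVersion("qpcrpanel"))
  )
  structure(list(
    demographics = demographics,
    baseline_panel = baseline_panel,
    longitudinal_panel = longitudinal_panel,
    correlations = correlations,
    pca = pca,
    pc_panel = pc_panel,
    clinical = clinical,
    methylation = methylation,
    manifest = manifest
  ), class = "pipeline_result")
}

#' Write a pipeline report bundle
#'
#' Writes each result as a delimited table (demographics, the two gene
#' panels, the PC panel, correlation matrix, scree/loadings/contributions/
#' scores, clinical and methylation correlations), plus `manifest.json` and
#' a short human-readable `summary.txt`.  Flagged rows are rendered with
#' their flag, never as bare numbers.
#'
#' @param results a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @param digits number of significant digits for floats in `summary.txt`.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(results, dir, digits = 4L) {
  stopifnot(inherits(results, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(obj, name, rn = FALSE) {
    path <- file.path(dir, name)
    write.csv(obj, path, row.names = rn)
    written <<- c(written, path)
  }
  put(results$demographics, "demographics.csv")
  put(as.data.frame(results$baseline_panel), "baseline_panel.csv")
  put(as.data.frame(results$longitudinal_panel), "longitudinal_panel.csv")
  put(as.data.frame(results$pc_panel), "pc_panel.csv")
  put(round(results$correlations$r, 6L), "correlation_matrix.csv", rn = TRUE)
  scree <- data.frame(dimension = names(results$pca$eigenvalues),
                      eigenvalue = unname(results$pca$eigenvalues),
                      percent_variance =
                        unname(results$pca$percent_variance))
  put(scree, "pca_scree.csv")
  put(round(results$pca$loadings, 6L), "pca_loadings.csv", rn = TRUE)
  put(round(results$pca$contributions, 4L), "pca_contributions.csv", rn = TRUE)
  put(round(results$pca$scores, 6L), "pca_scores.csv", rn = TRUE)
  if (!is.null(results$clinical)) put(results$clinical, "clinical_spearman.csv")
  if (!is.null(results$methylation))
    put(results$methylation, "methylation_correlations.csv")
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(results$manifest, mpath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, mpath)

  fthr <- results$manifest$config$fdr_threshold
  fmt_panel <- function(panel, label) {
    sig <- !panel$flagged & panel$p_fdr < fthr
    c(sprintf("%s panel (n = %d, B = %d):", label,
              panel$n_used[1L], panel$B[1L]),
      vapply(seq_len(nrow(panel)), function(i) {
        if (panel$flagged[i])
          sprintf("  %-6s FLAGGED (%s)", panel$gene[i], panel$flag_reason[i])
        else
          sprintf("  %-6s OR = %s [%s, %s], p_perm = %s, p_fdr = %s%s",
                  panel$gene[i],
                  signif(panel$or[i], digits), signif(panel$ci_low[i], digits),
                  signif(panel$ci_high[i], digits),
                  signif(panel$p_perm[i], digits),
                  signif(panel$p_fdr[i], digits),
                  if (sig[i]) " *" else "")
      }, character(1L)),
      sprintf("  %d of %d below FDR threshold %s", sum(sig), nrow(panel),
              fthr))
  }
  lines <- c(
    "qpcrpanel pipeline summary",
    sprintf("seed = %d", results$manifest$config$seed),
    "",
    fmt_panel(results$baseline_panel, "baseline"), "",
    fmt_panel(results$longitudinal_panel, "longitudinal"), "",
    fmt_panel(results$pc_panel, "principal components"), "",
    sprintf("PCA percent variance: %s",
            paste(signif(results$pca$percent_variance, 3L), collapse = ", ")),
    if (is.null(results$methylation))
      "methylation: not provided"
    else
      sprintf("methylation: %d CpGs tested, %d flagged",
              nrow(results$methylation), sum(!is.na(results$methylation$flag)))
  )
  spath <- file.path(dir, "summary.txt")
  writeLines(lines, spath)
  invisible(c(written, spath))
}
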