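# Co-expression structure of the gene panel: pairwise Pearson correlation,
# principal-component analysis with variable contributions, and group tests
# on component scores.

#' Pairwise Pearson correlation of the panel
#'
#' Pairwise-complete Pearson correlation per gene pair with the two-sided
#' t-based p-value and the number of complete pairs.  Constant genes give
#' flagged (NA) pairs.
#'
#' @param expr [expr_matrix()] (any scale).
#' @return a `correlation_matrix_result` list: `r`, `p`, `n` (gene x gene
#'   matrices) and `flagged` (character vector of constant genes).
#' @export
correlation_matrix <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- unclass(expr)
  G <- ncol(v)
  genes <- colnames(v)
  r <- p <- n <- matrix(NA_real_, G, G, dimnames = list(genes, genes))
  diag(r) <- 1
  diag(p) <- 0
  diag(n) <- colSums(!is.na(v))
  const <- apply(v, 2L, function(x) var(x, na.rm = TRUE) == 0 ||
                   sum(!is.na(x)) < 3L)
  for (i in seq_len(G - 1L)) {
    for (j in seq((i + 1L), G)) {
      if (const[i] || const[j]) next
      ok <- complete.cases(v[, c(i, j)])
      if (sum(ok) < 3L) next
      ct <- cor.test(v[ok, i], v[ok, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      n[i, j] <- n[j, i] <- sum(ok)
    }
  }
  structure(list(r = r, p = p, n = n, flagged = genes[const]),
            class = "correlation_matrix_result")
}

#' Principal-component analysis of the expression panel
#'
#' Column-centered (and by default unit-variance scaled, i.e.
#' correlation-matrix) PCA of the complete-case submatrix.  Eigenvector
#' signs follow a deterministic convention - each component is flipped so
#' that its largest-magnitude loading is positive - so results do not depend
#' on the linear-algebra backend.  Variable contributions are the squared
#' loadings expressed as percentages, summing to 100 within each dimension.
#'
#' @param expr [expr_matrix()]; rows with any missing value are dropped.
#' @param scale if `TRUE` (default) scale columns to unit variance.
#' @return a `pca_result` list: `eigenvalues`, `percent_variance`,
#'   `loadings` (genes x dims), `contributions` (percent, genes x dims),
#'   `scores` (subjects x dims), `center`, `scale`, `n_used`.
#' @export
run_pca <- function(expr, scale = TRUE) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- unclass(expr)
  keep <- complete.cases(v)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L) stop_named("PCA needs at least 2 complete subjects")
  pc <- prcomp(v, center = TRUE, scale. = scale)
  load <- pc$rotation
  scores <- pc$x
  # deterministic sign convention
  for (k in seq_len(ncol(load))) {
    jmax <- which.max(abs(load[, k]))
    if (load[jmax, k] < 0) {
      load[, k] <- -load[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- pc$sdev^2
  contrib <- sweep(load^2, 2L, colSums(load^2), "/") * 100
  dims <- paste0("PC", seq_along(ev))
  names(ev) <- dims
  colnames(load) <- colnames(contrib) <- colnames(scores) <- dims
  structure(list(
    eigenvalues = ev,
    percent_variance = 100 * ev / sum(ev),
    loadings = load,
    contributions = contrib,
    scores = scores,
    center = pc$center,
    scale = if (scale) pc$scale else NULL,
    n_used = nrow(v)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d subjects, %d dimensions>\n",
              x$n_used, length(x$eigenvalues)))
  cat("percent variance:",
      paste(sprintf("%.1f", x$percent_variance), collapse = ", "), "\n")
  invisible(x)
}

#' Group test on principal-component scores
#'
#' One covariate-adjusted logistic regression with the first `n_components`
#' score vectors entered jointly (the default) or one marginal model per
#' component; per-component permutation p-values by label permutation with
#' the scores fixed, and Benjamini-Hochberg adjustment across the tested
#' components.
#'
#' @param pca a [run_pca()] result.
#' @param cohort cohort sample sheet.
#' @param n_components number of leading components tested.
#' @param joint if `TRUE`, all components enter one model; otherwise one
#'   marginal model per component.
#' @inheritParams gene_panel_test
#' @return a `gene_panel_result` data frame (family `"pc"`, one row per
#'   component).
#' @export
pc_group_test <- function(pca, cohort, n_components = 3L,
                          B = 10000L, seed = 1L, smooth = FALSE, joint = TRUE,
                          covariates = c("age", "sex", "cpz_eq"),
                          case_group = "converter") {
  stopifnot(inherits(pca, "pca_result"))
  if (n_components > ncol(pca$scores))
    stop_named("n_components exceeds the available %d dimensions",
               ncol(pca$scores))
  scores <- pca$scores[, seq_len(n_components), drop = FALSE]
  subjects <- intersect(rownames(scores), cohort$subject_id)
  if (length(subjects) == 0L)
    stop_named("PCA scores and cohort share no subjects")
  scores <- scores[subjects, , drop = FALSE]
  mf <- cohort_model_frame(cohort, subjects, covariates, case_group)
  rows <- lapply(seq_len(n_components), function(k) {
    others <- if (joint && n_components > 1L)
      as.data.frame(scores[, -k, drop = FALSE]) else NULL
    covs <- if (is.null(others)) mf$covariates else
      cbind(others, mf$covariates)
    kseed <- child_seed(seed, 1000L + k)
    fit <- fit_logistic(mf$y, scores[, k], covs)
    perm <- permutation_pvalue(mf$y, scores[, k], covs,
                               B = B, seed = kseed, smooth = smooth)
    data.frame(gene = colnames(scores)[k], beta = fit$beta, or = fit$or,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               p_param = fit$p_param, p_perm = perm$p_perm,
               n_used = fit$n_used, n_perm_fail = perm$n_fail,
               B = perm$B, seed = kseed,
               flagged = fit$flagged, flag_reason = fit$flag_reason,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- fdr_adjust(res$p_perm)
  res <- res[, c("gene", "beta", "or", "ci_low", "ci_high", "p_param",
                 "p_perm", "p_fdr", "n_used", "n_perm_fail", "B", "seed",
                 "flagged", "flag_reason")]
  structure(res, family = "pc", covariates = covariates, joint = joint,
            class = c("gene_panel_result", "data.frame"))
}
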