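# Clinical-score correlations (including the CAARMS composite) and
# CpG-methylation / expression correlations.

#' CAARMS composite score
#'
#' Sum over the four first CAARMS subscales of global rating (0-6) times
#' frequency (0-6); an integer in `[0, 144]`.
#'
#' @param ratings,frequencies integer vectors of length 4, or n x 4 matrices
#'   / data frames for multiple subjects.
#' @return integer composite score (vector of length n for matrix input).
#' @export
caarms_composite <- function(ratings, frequencies) {
  r <- as.matrix(ratings)
  f <- as.matrix(frequencies)
  if (ncol(r) == 1L && nrow(r) == 4L) r <- t(r)
  if (ncol(f) == 1L && nrow(f) == 4L) f <- t(f)
  if (ncol(r) != 4L || ncol(f) != 4L || nrow(r) != nrow(f))
    stop_named("ratings and frequencies must each have 4 subscale values")
  if (any(is.na(r)) || any(is.na(f)) ||
      any(r < 0 | r > 6) || any(f < 0 | f > 6))
    stop_named("CAARMS ratings and frequencies must be in [0, 6]")
  as.integer(round(rowSums(r * f)))
}

#' Spearman correlation of expression with clinical scores
#'
#' Pairwise-complete Spearman correlation (average ranks for ties) between
#' each column of `values` and each clinical score, two-sided p-values: the
#' exact rank-permutation distribution for n <= 10 without ties, the
#' t approximation otherwise.  Pairs with a constant input are flagged.
#'
#' @param values numeric matrix (subjects x variables), e.g. z-scored
#'   expression or PC scores, with subject rownames.
#' @param scores numeric matrix or data frame of clinical scores with
#'   subject rownames (or a `subject_id` column).
#' @return data frame: `variable`, `score`, `rho`, `p_value`, `n`, `flag`.
#' @export
clinical_spearman <- function(values, scores) {
  v <- as.matrix(values)
  if (is.data.frame(scores) && "subject_id" %in% names(scores)) {
    rn <- as.character(scores$subject_id)
    scores <- as.matrix(scores[, setdiff(names(scores), "subject_id"),
                               drop = FALSE])
    rownames(scores) <- rn
  } else {
    scores <- as.matrix(scores)
  }
  if (is.null(rownames(v)) || is.null(rownames(scores)))
    stop_named("values and scores must carry subject IDs")
  common <- intersect(rownames(v), rownames(scores))
  if (length(common) < 4L) stop_named("need >= 4 shared subjects")
  v <- v[common, , drop = FALSE]
  scores <- scores[common, , drop = FALSE]
  out <- list()
  for (a in colnames(v)) for (b in colnames(scores)) {
    ok <- complete.cases(v[, a], scores[, b])
    x <- v[ok, a]; y <- scores[ok, b]
    n <- length(x)
    if (n < 4L || var(x) == 0 || var(y) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        variable = a, score = b, rho = NA_real_, p_value = NA_real_,
        n = n, flag = if (n < 4L) "too few pairs" else "constant input",
        stringsAsFactors = FALSE)
      next
    }
    res <- spearman_test(x, y)
    out[[length(out) + 1L]] <- data.frame(
      variable = a, score = b, rho = res$rho, p_value = res$p, n = n,
      flag = NA_character_, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# rho by average ranks; p exact (rank-permutation distribution, via
# cor.test's AS 89 evaluation) for small untied samples, t approximation
# otherwise.
spearman_test <- function(x, y) {
  rho <- cor(x, y, method = "spearman")
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10L && !ties) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p = min(p, 1))
}

#' Methylation-expression correlation per CpG
#'
#' Pearson correlation between each CpG's beta values and the expression of
#' its mapped gene, over the shared subjects; two-sided t-based p, with
#' Benjamini-Hochberg adjustment across all tested CpGs reported alongside
#' the raw p.  Constant beta columns are flagged and excluded from the
#' adjustment.
#'
#' @param meth beta-value data frame (`subject_id` column plus one column
#'   per CpG) or matrix with subject rownames; values in `[0, 1]`.
#' @param expr [expr_matrix()] of the matched expression values (default
#'   usage: baseline z-scores).
#' @param map data frame `cpg_id`, `gene`, `region` mapping every tested CpG
#'   to one panel gene.
#' @return data frame: `cpg_id`, `gene`, `region`, `r`, `p_value`, `p_fdr`,
#'   `n`, `sign`, `flag`.
#' @export
methylation_expression_correlation <- function(meth, expr, map) {
  if (is.data.frame(meth)) {
    if (!"subject_id" %in% names(meth))
      stop_named("methylation table must have a 'subject_id' column")
    rn <- as.character(meth$subject_id)
    meth <- as.matrix(meth[, setdiff(names(meth), "subject_id"),
                           drop = FALSE])
    rownames(meth) <- rn
  }
  stopifnot(inherits(expr, "expr_matrix"))
  need <- c("cpg_id", "gene", "region")
  if (!all(need %in% names(map)))
    stop_named("map must have columns: %s", paste(need, collapse = ", "))
  if (any(meth < 0 | meth > 1, na.rm = TRUE))
    stop_named("beta values must lie in [0, 1]")
  cpgs <- intersect(colnames(meth), map$cpg_id)
  if (length(cpgs) == 0L) stop_named("no mapped CpGs present in the matrix")
  common <- intersect(rownames(meth), rownames(expr))
  if (length(common) < 4L)
    stop_named("need >= 4 subjects shared between methylation and expression")
  meth <- meth[common, , drop = FALSE]
  ev <- unclass(expr)[common, , drop = FALSE]
  rows <- lapply(cpgs, function(cg) {
    gene <- map$gene[match(cg, map$cpg_id)]
    region <- map$region[match(cg, map$cpg_id)]
    if (!gene %in% colnames(ev))
      return(data.frame(cpg_id = cg, gene = gene, region = region,
                        r = NA_real_, p_value = NA_real_, n = 0L,
                        sign = NA_character_, flag = "gene not in panel",
                        stringsAsFactors = FALSE))
    ok <- complete.cases(meth[, cg], ev[, gene])
    x <- meth[ok, cg]; y <- ev[ok, gene]
    if (sum(ok) < 4L || var(x) == 0 || var(y) == 0)
      return(data.frame(cpg_id = cg, gene = gene, region = region,
                        r = NA_real_, p_value = NA_real_, n = sum(ok),
                        sign = NA_character_,
                        flag = if (sum(ok) < 4L) "too few pairs"
                               else "constant input",
                        stringsAsFactors = FALSE))
    ct <- cor.test(x, y, method = "pearson")
    data.frame(cpg_id = cg, gene = gene, region = region,
               r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
               sign = if (ct$estimate >= 0) "positive" else "negative",
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$p_fdr[ok] <- fdr_adjust(out$p_value[ok])
  out[, c("cpg_id", "gene", "region", "r", "p_value", "p_fdr", "n",
          "sign", "flag")]
}
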