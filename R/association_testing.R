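# Covariate-adjusted logistic regression per gene with a permutation null on
# the Wald p-value, Benjamini-Hochberg FDR across the panel, and the
# demographics comparison table (Mann-Whitney / Fisher).

#' Covariate-adjusted logistic regression for one predictor
#'
#' Fits `outcome ~ predictor + covariates` by maximum likelihood
#' (binomial family, logit link) and reports the predictor coefficient as a
#' log-odds ratio with Wald 95% CI and two-sided Wald p-value.  Degenerate
#' fits ((quasi-)separation, non-convergence, constant predictor) are
#' returned flagged rather than as silent numbers.
#'
#' @param outcome binary vector (0/1 or logical), 1 = case.
#' @param predictor numeric vector, typically standardized expression, so
#'   `beta` is the log-odds per 1 SD.
#' @param covariates optional data frame or matrix of numeric adjustment
#'   covariates.
#' @return a `logistic_fit` list: `beta`, `se`, `or`, `ci_low`, `ci_high`
#'   (OR scale), `p_param`, `n_used`, `converged`, `flagged`, `flag_reason`.
#' @export
fit_logistic <- function(outcome, predictor, covariates = NULL) {
  d <- assemble_design(outcome, predictor, covariates)
  out <- list(beta = NA_real_, se = NA_real_, or = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, p_param = NA_real_,
              n_used = d$n, converged = FALSE, flagged = TRUE,
              flag_reason = NA_character_)
  class(out) <- "logistic_fit"
  if (length(unique(d$y)) < 2L) {
    out$flag_reason <- "single outcome class"
    return(out)
  }
  if (var(d$X[, 2L]) == 0) {
    out$flag_reason <- "constant predictor"
    return(out)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(d$X, d$y, family = binomial(), control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  if (fit$rank < ncol(d$X) || anyNA(beta)) {
    out$flag_reason <- "rank-deficient design"
    return(out)
  }
  # unscaled covariance as in summary.glm (dispersion = 1 for binomial)
  p1 <- seq_len(fit$rank)
  cov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- numeric(length(beta))
  se[fit$qr$pivot[p1]] <- sqrt(diag(cov))
  out$beta <- unname(beta[2L])
  out$se <- unname(se[2L])
  out$or <- exp(out$beta)
  out$ci_low <- exp(out$beta - 1.96 * out$se)
  out$ci_high <- exp(out$beta + 1.96 * out$se)
  out$p_param <- 2 * pnorm(-abs(out$beta / out$se))
  out$converged <- isTRUE(fit$converged)
  separated <- sep_warn && abs(out$beta) > 10
  out$flagged <- !out$converged || separated
  out$flag_reason <- if (separated) "separation"
                     else if (!out$converged) "non-convergence"
                     else NA_character_
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("<logistic_fit: FLAGGED (%s), n = %d>\n",
                x$flag_reason, x$n_used))
  } else {
    cat(sprintf(
      "<logistic_fit: OR = %.3f [%.3f, %.3f], p = %.4g, n = %d>\n",
      x$or, x$ci_low, x$ci_high, x$p_param, x$n_used))
  }
  invisible(x)
}

# Complete-case design matrix: intercept, predictor, covariates.
assemble_design <- function(outcome, predictor, covariates = NULL) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop_named("outcome must be binary 0/1")
  X <- cbind(`(Intercept)` = 1, predictor = as.numeric(predictor))
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    storage.mode(cm) <- "double"
    X <- cbind(X, cm)
  }
  keep <- complete.cases(cbind(y, X))
  if (!any(keep)) stop_named("no complete cases")
  list(y = y[keep], X = X[keep, , drop = FALSE], n = sum(keep))
}

#' Permutation p-value for the predictor coefficient
#'
#' Null distribution by label permutation: the binary outcome is shuffled
#' uniformly at random over subjects while each subject keeps its own
#' predictor and covariate values, the logistic model is refit, and the
#' two-sided Wald p-value of the predictor recomputed.  The reported
#' permutation p is `#\{b : p(b) <= p(observed)\} / B`; ties therefore count
#' against rejection, and a constant predictor yields p = 1.  Permutation
#' fits that fail (separation, non-convergence) enter with p = 1 and are
#' counted in `n_fail`.  The tie comparison carries a relative guard of
#' 1e-8 so that permutations reproducing the observed statistic exactly
#' (e.g. identical 2x2 tables in a different row order) count as ties
#' despite last-bit floating-point differences.
#'
#' @inheritParams fit_logistic
#' @param B number of random permutations (the study convention is 10000).
#' @param seed integer seed for the permutation stream.
#' @param smooth if `TRUE`, report the (k+1)/(B+1) estimator, which cannot
#'   be exactly zero; default is the plain k/B ratio.
#' @return list with `p_perm`, `k`, `B`, `n_fail`, `p_obs`, `seed`, `smooth`.
#' @export
permutation_pvalue <- function(outcome, predictor, covariates = NULL,
                               B = 10000L, seed = 1L, smooth = FALSE) {
  if (B < 1L) stop_named("B must be >= 1")
  d <- assemble_design(outcome, predictor, covariates)
  obs <- cpp_logistic_wald(d$X, d$y)
  p_obs <- if (isTRUE(obs$ok)) obs$p[2L] else 1.0
  perm <- with_seed(seed, cpp_perm_pvals(d$X, d$y, 2L, as.integer(B)))
  # "<=" with a relative guard: permutations that reproduce the observed
  # statistic exactly (e.g. tied 2x2 tables) must count as ties even though
  # row order perturbs the floating-point result in its last bits
  k <- sum(perm$p <= p_obs + 1e-8 * (p_obs + 1))
  if (perm$n_fail > 0)
    message(sprintf("%d of %d permutation fits failed and were counted as p = 1",
                    perm$n_fail, B))
  list(p_perm = if (smooth) (k + 1) / (B + 1) else k / B,
       k = k, B = as.integer(B), n_fail = perm$n_fail,
       p_obs = p_obs, seed = seed, smooth = smooth)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_named("p-values must be in [0, 1] and non-missing")
  p.adjust(p, method = "BH")
}

# Extract outcome + covariates from a cohort sample sheet, aligned to a set
# of subject IDs.
cohort_model_frame <- function(cohort, subjects,
                               covariates = c("age", "sex", "cpz_eq"),
                               case_group = "converter") {
  idx <- match(subjects, cohort$subject_id)
  if (anyNA(idx))
    stop_named("expression subjects missing from cohort: %s",
               paste(utils::head(subjects[is.na(idx)], 5L), collapse = ", "))
  cc <- cohort[idx, , drop = FALSE]
  y <- as.numeric(cc$group == case_group)
  covs <- NULL
  if (length(covariates) > 0) {
    covs <- as.data.frame(lapply(covariates, function(v) {
      if (!v %in% names(cc)) stop_named("covariate '%s' not in cohort", v)
      col <- cc[[v]]
      if (v == "sex") as.numeric(col == "male") else as.numeric(col)
    }), col.names = covariates)
  }
  list(y = y, covariates = covs, cohort = cc)
}

#' Per-gene group test across an expression panel
#'
#' For each gene: covariate-adjusted logistic regression of conversion
#' status on the standardized expression value, permutation p-value of the
#' predictor coefficient, then Benjamini-Hochberg adjustment of the
#' permutation p-values across the genes of this analysis family only.
#'
#' @param expr [expr_matrix()] of `zscore` or `change_zscore` values.
#' @param cohort cohort sample sheet (see [read_inputs()]); must contain
#'   `subject_id`, `group` and the covariate columns.
#' @param family analysis family label (`"baseline"` or `"longitudinal"`);
#'   FDR is computed within the family only.
#' @param B,seed,smooth passed to [permutation_pvalue()]; each gene uses a
#'   deterministic child seed derived from `seed`.
#' @param covariates cohort columns used as adjustment covariates; `sex` is
#'   coded male = 1.
#' @param case_group cohort group treated as the outcome's 1 level.
#' @return a `gene_panel_result` data frame (one row per gene: `beta`, `or`,
#'   `ci_low`, `ci_high`, `p_param`, `p_perm`, `p_fdr`, `n_used`, `B`,
#'   `seed`, `flagged`, `flag_reason`), with the family and covariate
#'   specification as attributes.
#' @export
gene_panel_test <- function(expr, cohort,
                            family = c("baseline", "longitudinal", "pc"),
                            B = 10000L, seed = 1L, smooth = FALSE,
                            covariates = c("age", "sex", "cpz_eq"),
                            case_group = "converter") {
  family <- match.arg(family)
  stopifnot(inherits(expr, "expr_matrix"))
  subjects <- intersect(rownames(expr), cohort$subject_id)
  if (length(subjects) == 0L)
    stop_named("expression matrix and cohort share no subjects")
  mf <- cohort_model_frame(cohort, subjects, covariates, case_group)
  v <- unclass(expr)[subjects, , drop = FALSE]
  rows <- lapply(seq_len(ncol(v)), function(j) {
    gene <- colnames(v)[j]
    gseed <- child_seed(seed, j)
    fit <- fit_logistic(mf$y, v[, j], mf$covariates)
    perm <- permutation_pvalue(mf$y, v[, j], mf$covariates,
                               B = B, seed = gseed, smooth = smooth)
    data.frame(gene = gene, beta = fit$beta, or = fit$or,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               p_param = fit$p_param, p_perm = perm$p_perm,
               n_used = fit$n_used, n_perm_fail = perm$n_fail,
               B = perm$B, seed = gseed,
               flagged = fit$flagged, flag_reason = fit$flag_reason,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- fdr_adjust(res$p_perm)
  res <- res[, c("gene", "beta", "or", "ci_low", "ci_high", "p_param",
                 "p_perm", "p_fdr", "n_used", "n_perm_fail", "B", "seed",
                 "flagged", "flag_reason")]
  structure(res, family = family, covariates = covariates,
            class = c("gene_panel_result", "data.frame"))
}

#' Demographic and clinical comparison table
#'
#' Per-variable two-group comparison in the conventional cohort-description
#' layout: continuous variables by two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test, reported as group mean (SD); categorical variables by
#' two-sided Fisher exact test, reported as counts.  Variables with a single
#' unique value are flagged and not tested.
#'
#' @param cohort cohort sample sheet with a `group` column.
#' @param continuous,categorical variable names; defaults cover the columns
#'   the synthetic generator emits and silently skip absent ones.
#' @param case_group,reference_group the two group labels to compare.
#' @return data frame: variable, type, per-group summary, `p_value`, `test`,
#'   `flag`.
#' @export
cohort_summary <- function(cohort,
                           continuous = c("age", "followup_months",
                                          "bprs_m0", "bprs_mf",
                                          "cgi_m0", "cgi_mf",
                                          "caarms_m0", "caarms_mf"),
                           categorical = c("sex", "tobacco", "cannabis",
                                           "medicated"),
                           case_group = "converter",
                           reference_group = "non-converter") {
  stopifnot("group" %in% names(cohort))
  g1 <- cohort$group == case_group
  g2 <- cohort$group == reference_group
  if (!any(g1) || !any(g2))
    stop_named("both groups must be present in the cohort")
  continuous <- intersect(continuous, names(cohort))
  categorical <- intersect(categorical, names(cohort))
  row_for <- function(v, type) {
    x <- cohort[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      return(data.frame(variable = v, type = type,
                        converters = NA_character_,
                        non_converters = NA_character_,
                        p_value = NA_real_, test = NA_character_,
                        flag = "constant variable",
                        stringsAsFactors = FALSE))
    }
    if (type == "continuous") {
      x1 <- x[g1]; x2 <- x[g2]
      p <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE)$p.value)
      data.frame(variable = v, type = type,
                 converters = sprintf("%.2f (%.2f)", mean(x1, na.rm = TRUE),
                                      sd(x1, na.rm = TRUE)),
                 non_converters = sprintf("%.2f (%.2f)", mean(x2, na.rm = TRUE),
                                          sd(x2, na.rm = TRUE)),
                 p_value = p, test = "mann-whitney", flag = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(factor(cohort$group, levels = c(case_group,
                                                   reference_group)), x)
      p <- fisher.test(tab)$p.value
      fmt <- function(r) paste(r, collapse = "/")
      data.frame(variable = v, type = type,
                 converters = fmt(tab[1L, ]), non_converters = fmt(tab[2L, ]),
                 p_value = p, test = "fisher", flag = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }
  out <- rbind(
    do.call(rbind, lapply(continuous, row_for, type = "continuous")),
    do.call(rbind, lapply(categorical, row_for, type = "categorical"))
  )
  rownames(out) <- NULL
  out
}
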