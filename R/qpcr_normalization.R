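# Livak (2^-ddCt) normalization of raw qPCR Ct values against a reference
# gene, reference-group z-scoring, and longitudinal change matrices.

#' Expression matrix container
#'
#' A numeric matrix (subjects in rows, target genes in columns) tagged with
#' the scale of its values: `delta_ct` (Ct_target - Ct_reference, cycles),
#' `rq` (Livak relative quantity, 2^-ddCt), `zscore` (reference-group
#' z-score of RQ), `change` (RQ difference follow-up minus baseline) or
#' `change_zscore`.
#'
#' @param values numeric matrix with subject IDs as rownames and gene names
#'   as colnames.
#' @param scale one of `"delta_ct"`, `"rq"`, `"zscore"`, `"change"`,
#'   `"change_zscore"`, `"log2rq"`.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, scale) {
  scale <- match.arg(scale, c("delta_ct", "rq", "zscore", "change",
                              "change_zscore", "log2rq"))
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (scale == "rq" && any(values <= 0, na.rm = TRUE))
    stop_named("relative quantities must be positive")
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix: %d subjects x %d genes, scale = %s>\n",
              nrow(x), ncol(x), attr(x, "scale")))
  print(utils::head(unclass(x), 4L))
  invisible(x)
}

expr_scale <- function(x) attr(x, "scale")

# Coerce a wide Ct data frame (subject_id column + one column per gene) into
# a numeric matrix with subject rownames.
ct_as_matrix <- function(ct) {
  if (is.data.frame(ct)) {
    if (!"subject_id" %in% names(ct))
      stop_named("Ct table must have a 'subject_id' column")
    m <- as.matrix(ct[, setdiff(names(ct), "subject_id"), drop = FALSE])
    rownames(m) <- as.character(ct$subject_id)
  } else {
    m <- as.matrix(ct)
    if (is.null(rownames(m)))
      stop_named("Ct matrix must carry subject IDs as rownames")
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m)))
    stop_named("duplicated subject IDs in Ct table")
  m
}

#' Reference-gene normalization (delta-Ct)
#'
#' Subtracts the reference-gene Ct from every target-gene Ct per subject.
#' Subjects with a missing reference-gene value cannot be normalized and are
#' dropped with a warning.
#'
#' @param ct wide Ct table: data frame with `subject_id` plus one column per
#'   gene (targets and the reference), or an equivalent matrix with subject
#'   rownames.
#' @param reference_gene name of the housekeeping gene column.
#' @return [expr_matrix()] on the `delta_ct` scale (targets only).
#' @export
delta_ct <- function(ct, reference_gene = "GAPDH") {
  m <- ct_as_matrix(ct)
  if (!reference_gene %in% colnames(m))
    stop_named("reference gene '%s' not found in Ct table", reference_gene)
  ref <- m[, reference_gene]
  keep <- !is.na(ref)
  if (!all(keep))
    warning(sprintf("dropping %d subject(s) with missing reference-gene Ct",
                    sum(!keep)), call. = FALSE)
  targets <- setdiff(colnames(m), reference_gene)
  out <- m[keep, targets, drop = FALSE] - ref[keep]
  expr_matrix(out, "delta_ct")
}

#' Livak relative expression (2^-ddCt)
#'
#' Computes ddCt against a per-gene calibrator and transforms to relative
#' quantities RQ = 2^(-ddCt), so one cycle less than the calibrator doubles
#' the reported expression.
#'
#' @param dct `expr_matrix` on the `delta_ct` scale.
#' @param calibrator `"reference_group_mean"` (default; mean delta-Ct of the
#'   reference-group subjects), `"global_mean"`, or `"fixed"`.
#' @param groups,reference_group group label per subject of `dct` (named by
#'   subject or in row order) and the label of the calibrator group; required
#'   for `"reference_group_mean"`.
#' @param fixed_values named per-gene calibrator delta-Ct, for `"fixed"`.
#' @return [expr_matrix()] on the `rq` scale.
#' @export
relative_expression <- function(dct,
                                calibrator = c("reference_group_mean",
                                               "global_mean", "fixed"),
                                groups = NULL,
                                reference_group = "non-converter",
                                fixed_values = NULL) {
  stopifnot(inherits(dct, "expr_matrix"), expr_scale(dct) == "delta_ct")
  calibrator <- match.arg(calibrator)
  v <- unclass(dct)
  cal <- switch(calibrator,
    reference_group_mean = {
      g <- align_groups(groups, rownames(v))
      idx <- which(g == reference_group)
      if (length(idx) == 0L)
        stop_named("no subjects in calibrator group '%s'", reference_group)
      colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
    },
    global_mean = colMeans(v, na.rm = TRUE),
    fixed = {
      if (is.null(fixed_values))
        stop_named("calibrator = 'fixed' requires fixed_values")
      expand_gene_vector(fixed_values, colnames(v), "fixed_values")
    })
  if (any(!is.finite(cal)))
    stop_named("calibrator undefined for gene(s): %s",
               paste(colnames(v)[!is.finite(cal)], collapse = ", "))
  ddct <- sweep(v, 2L, cal, "-")
  expr_matrix(2^(-ddct), "rq")
}

align_groups <- function(groups, subjects) {
  if (is.null(groups)) stop_named("group labels are required")
  if (!is.null(names(groups))) {
    missing <- setdiff(subjects, names(groups))
    if (length(missing) > 0)
      stop_named("no group label for subject(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", "))
    return(as.character(groups[subjects]))
  }
  if (length(groups) != length(subjects))
    stop_named("groups must be named by subject or match the row count")
  as.character(groups)
}

#' Reference-group z-scores
#'
#' Standardizes each gene on the mean and SD (n-1 denominator) computed from
#' the reference-group subjects only, then applies that standardization to
#' all subjects.  After z-scoring, the calibrator choice made in
#' [relative_expression()] is provably irrelevant.
#'
#' @param x `expr_matrix` on the `rq`, `log2rq` or `change` scale.
#' @param groups group label per subject (named by subject or in row order).
#' @param reference_group label of the standardizing group.
#' @return [expr_matrix()] on the `zscore` (or `change_zscore`) scale.
#' @export
zscore_on_reference <- function(x, groups, reference_group = "non-converter") {
  stopifnot(inherits(x, "expr_matrix"),
            expr_scale(x) %in% c("rq", "log2rq", "change"))
  v <- unclass(x)
  g <- align_groups(groups, rownames(v))
  idx <- which(g == reference_group)
  if (length(idx) < 2L)
    stop_named("need >= 2 reference-group subjects to standardize")
  mu <- colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
  sdv <- apply(v[idx, , drop = FALSE], 2L, sd, na.rm = TRUE)
  if (any(!is.finite(sdv) | sdv <= 0))
    stop_named("zero or undefined reference-group SD for gene(s): %s",
               paste(colnames(v)[!is.finite(sdv) | sdv <= 0], collapse = ", "))
  z <- sweep(sweep(v, 2L, mu, "-"), 2L, sdv, "/")
  expr_matrix(z, if (expr_scale(x) == "change") "change_zscore" else "zscore")
}

#' Longitudinal expression change
#'
#' Follow-up minus baseline relative expression per subject and gene,
#' complete-case: only subjects present at both time points are retained.
#'
#' @param m0,mf `expr_matrix` objects on the same scale (`rq` or `log2rq`)
#'   for baseline and follow-up.
#' @return [expr_matrix()] on the `change` scale.
#' @export
longitudinal_change <- function(m0, mf) {
  stopifnot(inherits(m0, "expr_matrix"), inherits(mf, "expr_matrix"))
  if (!identical(expr_scale(m0), expr_scale(mf)))
    stop_named("time points are on different scales (%s vs %s)",
               expr_scale(m0), expr_scale(mf))
  if (!expr_scale(m0) %in% c("rq", "log2rq"))
    stop_named("longitudinal change expects rq or log2rq matrices")
  common <- intersect(rownames(m0), rownames(mf))
  if (length(common) == 0L)
    stop_named("no subjects present at both time points")
  genes <- intersect(colnames(m0), colnames(mf))
  d <- unclass(mf)[common, genes, drop = FALSE] -
    unclass(m0)[common, genes, drop = FALSE]
  expr_matrix(d, "change")
}

#' Log2 transform of relative quantities
#'
#' @param rq `expr_matrix` on the `rq` scale.
#' @return [expr_matrix()] on the `log2rq` scale.
#' @export
log2_rq <- function(rq) {
  stopifnot(inherits(rq, "expr_matrix"), expr_scale(rq) == "rq")
  expr_matrix(log2(unclass(rq)), "log2rq")
}
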