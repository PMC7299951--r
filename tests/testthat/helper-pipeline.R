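# Shared shortcuts: normalization chain on a synthetic cohort, on the
# pipeline's default log2(RQ) analysis scale.

cohort_groups <- function(sc) {
  stats::setNames(sc$cohort$group, sc$cohort$subject_id)
}

baseline_z <- function(sc) {
  g <- cohort_groups(sc)
  rq <- relative_expression(delta_ct(sc$ct_m0), groups = g)
  zscore_on_reference(log2_rq(rq), g)
}

change_z <- function(sc) {
  g <- cohort_groups(sc)
  rq0 <- relative_expression(delta_ct(sc$ct_m0), groups = g)
  rqf <- relative_expression(delta_ct(sc$ct_mf), groups = g)
  chg <- longitudinal_change(log2_rq(rq0), log2_rq(rqf))
  zscore_on_reference(chg, g)
}

# build a per-subject data frame realizing a 2x2 outcome-by-exposure table
expand_2x2 <- function(n11, n10, n01, n00) {
  data.frame(
    y = c(rep(1, n11 + n10), rep(0, n01 + n00)),
    x = c(rep(1, n11), rep(0, n10), rep(1, n01), rep(0, n00))
  )
}
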