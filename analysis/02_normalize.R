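#!/usr/bin/env Rscript
# Normalize the raw Ct fixtures: delta-Ct against GAPDH, Livak 2^-ddCt
# relative quantities, z-scores standardized on the non-converters, and the
# longitudinal change matrix.  Also demonstrates that the calibrator choice
# is irrelevant after z-scoring.

suppressPackageStartupMessages(library(qpcrpanel))

fx <- "results/fixtures/study"
cohort <- read.csv(file.path(fx, "sample_sheet.csv"), check.names = FALSE)
groups <- setNames(cohort$group, cohort$subject_id)

dct0 <- delta_ct(read.csv(file.path(fx, "ct_m0.csv"), check.names = FALSE))
dctf <- delta_ct(read.csv(file.path(fx, "ct_mf.csv"), check.names = FALSE))
rq0 <- relative_expression(dct0, "reference_group_mean", groups = groups)
rqf <- relative_expression(dctf, "reference_group_mean", groups = groups)
z0 <- zscore_on_reference(log2_rq(rq0), groups)
chg <- longitudinal_change(log2_rq(rq0), log2_rq(rqf))
zc <- zscore_on_reference(chg, groups)

dir.create("results/expression", showWarnings = FALSE, recursive = TRUE)
save_mat <- function(m, name) {
  write.csv(data.frame(subject_id = rownames(m), unclass(m),
                       check.names = FALSE),
            file.path("results/expression", name), row.names = FALSE)
}
save_mat(rq0, "rq_m0.csv")
save_mat(z0, "zscore_m0.csv")
save_mat(zc, "zscore_change.csv")

z_alt <- zscore_on_reference(
  log2_rq(relative_expression(dct0, "global_mean")), groups)
cat(sprintf("baseline: %d subjects normalized; longitudinal: %d complete cases\n",
            nrow(z0), nrow(zc)))
cat(sprintf("max |z difference| between calibrator strategies: %.2e\n",
            max(abs(unclass(z0) - unclass(z_alt)))))
nc <- groups[rownames(z0)] == "non-converter"
cat(sprintf("non-converter z moments: mean in [%.1e, %.1e], sd in [%.6f, %.6f]\n",
            min(colMeans(unclass(z0)[nc, ])), max(colMeans(unclass(z0)[nc, ])),
            min(apply(unclass(z0)[nc, ], 2, sd)),
            max(apply(unclass(z0)[nc, ], 2, sd))))
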