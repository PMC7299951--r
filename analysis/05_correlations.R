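#!/usr/bin/env Rscript
# Clinical and epigenetic correlates: Spearman correlation of baseline
# expression with end-of-follow-up clinical scores (including the CAARMS
# composite), and Pearson correlation of CpG methylation with the matched
# gene's expression in the 25-subject subset.

suppressPackageStartupMessages(library(qpcrpanel))

fx <- "results/fixtures/study"
cohort <- read.csv(file.path(fx, "sample_sheet.csv"), check.names = FALSE)
groups <- setNames(cohort$group, cohort$subject_id)
z0 <- zscore_on_reference(
  log2_rq(relative_expression(
    delta_ct(read.csv(file.path(fx, "ct_m0.csv"), check.names = FALSE)),
    groups = groups)), groups)

clin <- clinical_spearman(
  unclass(z0),
  cohort[, c("subject_id", "bprs_mf", "cgi_mf", "panss_neg_mf",
             "caarms_mf")])
meth <- methylation_expression_correlation(
  read.csv(file.path(fx, "methylation.csv"), check.names = FALSE), z0,
  read.csv(file.path(fx, "cpg_map.csv"), check.names = FALSE))

dir.create("results/correlations", showWarnings = FALSE, recursive = TRUE)
write.csv(clin, "results/correlations/clinical_spearman.csv",
          row.names = FALSE)
write.csv(meth, "results/correlations/methylation.csv", row.names = FALSE)

top <- clin[order(-abs(clin$rho)), ][1:5, ]
cat("strongest expression-clinical correlations (Spearman):\n")
print(data.frame(top[, c("variable", "score")], rho = round(top$rho, 2),
                 p = signif(top$p_value, 2)), row.names = FALSE)
sig <- meth[!is.na(meth$p_fdr) & meth$p_fdr < 0.05, ]
raw <- meth[!is.na(meth$p_value) & meth$p_value < 0.05, ]
cat(sprintf("\nmethylation: %d of %d CpGs at raw p < 0.05, %d after BH (n = %d subjects)\n",
            nrow(raw), nrow(meth), nrow(sig), meth$n[1]))
top_m <- raw[order(raw$p_value), ][seq_len(min(8, nrow(raw))), ]
if (nrow(top_m) > 0)
  print(data.frame(top_m[, c("cpg_id", "gene", "region", "sign")],
                   r = round(top_m$r, 2), p = signif(top_m$p_value, 2)),
        row.names = FALSE)
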