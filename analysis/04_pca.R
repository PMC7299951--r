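#!/usr/bin/env Rscript
# Co-expression structure: pairwise Pearson correlation of the panel, PCA of
# the baseline z-scores, and the component-level group test (first three
# components entered jointly with age, sex and medication).

suppressPackageStartupMessages(library(qpcrpanel))

fx <- "results/fixtures/study"
cohort <- read.csv(file.path(fx, "sample_sheet.csv"), check.names = FALSE)
groups <- setNames(cohort$group, cohort$subject_id)
z0 <- zscore_on_reference(
  log2_rq(relative_expression(
    delta_ct(read.csv(file.path(fx, "ct_m0.csv"), check.names = FALSE)),
    groups = groups)), groups)

cm <- correlation_matrix(z0)
pca <- run_pca(z0)
pc <- pc_group_test(pca, cohort, n_components = 3, B = 2000, seed = 13)

dir.create("results/pca", showWarnings = FALSE, recursive = TRUE)
write.csv(round(cm$r, 4), "results/pca/correlation_matrix.csv")
write.csv(data.frame(dimension = names(pca$eigenvalues),
                     eigenvalue = unname(pca$eigenvalues),
                     percent_variance = unname(pca$percent_variance)),
          "results/pca/scree.csv", row.names = FALSE)
write.csv(round(pca$contributions, 2), "results/pca/contributions.csv")
write.csv(round(pca$scores, 4), "results/pca/scores.csv")
write.csv(as.data.frame(pc), "results/pca/pc_panel.csv", row.names = FALSE)

cat(sprintf("mean off-diagonal Pearson r: %.2f\n",
            mean(cm$r[lower.tri(cm$r)])))
cat(sprintf("variance explained by PC1+PC2: %.1f%% (%.1f%% and %.1f%%)\n",
            sum(pca$percent_variance[1:2]), pca$percent_variance[1],
            pca$percent_variance[2]))
cat("PC1 contributions (%):\n")
print(round(sort(pca$contributions[, "PC1"], decreasing = TRUE), 1))
cat(sprintf("PC1 group test: OR = %.2f [%.2f, %.2f], p_perm = %.4g\n",
            pc$or[1], pc$ci_low[1], pc$ci_high[1], pc$p_perm[1]))
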