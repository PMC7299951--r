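#!/usr/bin/env Rscript
# Generate the two synthetic cohorts every later stage consumes: the "study"
# cohort with the emulated group effects (baseline +0.8 SD on five of seven
# genes, longitudinal -0.6 SD on five genes, CpG-expression correlations in
# the methylation subset) and a zero-effect "null" cohort used for
# calibration checks.  Writes delimited pipeline inputs under
# results/fixtures/.

suppressPackageStartupMessages(library(qpcrpanel))

seed <- 2026L
dir.create("results/fixtures", showWarnings = FALSE, recursive = TRUE)

study <- generate_cohort(sim_config(seed = seed))
null <- generate_cohort(null_config(seed = seed + 1L))

p_study <- write_cohort_files(study, "results/fixtures/study")
p_null <- write_cohort_files(null, "results/fixtures/null")

n_mf <- sum(study$cohort$has_mf)
cat(sprintf("study cohort: %d subjects (36 converters / 56 non-converters), %d with follow-up\n",
            nrow(study$cohort), n_mf))
cat(sprintf("methylation subset: %d subjects, %d CpGs across %d genes\n",
            nrow(study$methylation), nrow(study$cpg_map),
            length(unique(study$cpg_map$gene))))
cat(sprintf("injected baseline effects (observed-SD units): %s\n",
            paste(names(study$truth$baseline_effects),
                  study$truth$baseline_effects, sep = "=", collapse = " ")))
cat("files:\n")
for (p in c(p_study, p_null)) cat(" ", p, "\n")
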