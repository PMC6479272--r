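#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Draws the default synthetic cohort (n = 173, 46-gene signature, planted
# immune-low/mixed/high subtypes, ~29% deaths / ~57% recurrences / ~73%
# responders) plus the Ct-level qPCR table that stage 2 re-normalizes, with
# 3% of expression cells knocked out to exercise the imputation step.

library(ovasig)

seed <- 1
out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(missing_rate = 0, seed = seed)
cohort <- generate_cohort(cfg)
print(cohort)

write_cohort(cohort, out_dir)

# Ct-level fixture: emitted from the complete matrix, then the matrix the
# analysis sees gets MCAR holes
ct <- emit_ct_table(cohort$expression)
ct_df <- data.frame(sample_id = rownames(ct$ct), ct$ct, check.names = FALSE)
write.table(ct_df, file.path(out_dir, "ct_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

holey <- inject_missing(cohort$expression, 0.03, seed = seed)
write_expression_tsv(holey, file.path(out_dir, "expression_missing.tsv"))

cat(sprintf("cohort written to %s: %d samples, %d genes, %d missing cells\n",
            out_dir, nrow(cohort$expression), ncol(cohort$expression),
            sum(is.na(holey))))
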