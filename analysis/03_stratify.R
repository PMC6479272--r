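#!/usr/bin/env Rscript
# Stage 3: correlation structure and immune subtype stratification.
#
# Computes the gene-gene correlation matrix with Holm-adjusted p-values,
# clusters patients on the full signature (uncentered Pearson, UPGMA),
# assigns immune-low/mixed/high labels, compares per-gene expression between
# the extreme subtypes with variance-guided tests, and tests the association
# of subtype with treatment response.

library(ovasig)

out_dir <- "results/stratify"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression_tsv("results/preprocess/expression_log2.tsv")
clinical <- read.delim("results/cohort/clinical.tsv")
truth <- read.delim("results/cohort/true_subtype.tsv")

corr <- correlation_matrix(expr)
strong <- sum(corr$r[upper.tri(corr$r)] > 0.5 &
                corr$p_adj[upper.tri(corr$p_adj)] < 0.001)
cat(sprintf("strong positive gene-gene correlations (r > 0.5, Holm p < 0.001): %d pairs\n",
            strong))
write.table(data.frame(gene = rownames(corr$r), round(corr$r, 4)),
            file.path(out_dir, "correlation_r.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = rownames(corr$p_adj), signif(corr$p_adj, 4)),
            file.path(out_dir, "correlation_p_holm.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

subtypes <- assign_subtypes(expr, default_signature())
print(subtypes)
agree <- mean(as.character(subtypes$labels[truth$sample_id]) ==
                truth$true_subtype, na.rm = TRUE)
nm <- truth$true_subtype != "mixed"
agree_nm <- mean(as.character(subtypes$labels[truth$sample_id[nm]]) ==
                   truth$true_subtype[nm], na.rm = TRUE)
cat(sprintf("agreement with simulated subtype: %.1f%% overall, %.1f%% on the planted low/high samples\n",
            100 * agree, 100 * agree_nm))
write.table(data.frame(sample_id = names(subtypes$labels),
                       subtype = as.character(subtypes$labels)),
            file.path(out_dir, "subtypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

extreme <- subtypes$labels %in% c("immune_low", "immune_high")
cmp <- compare_groups(
  expression_matrix(as.matrix(expr)[extreme, ], "log2"),
  droplevels(subtypes$labels[extreme]))
cat(sprintf("genes differing between immune-low and immune-high (Holm p < 0.05): %d of %d\n",
            sum(cmp$table$p_holm < 0.05), nrow(cmp$table)))
write.table(cmp$table, file.path(out_dir, "group_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tab <- table(droplevels(subtypes$labels[extreme]),
             clinical$response[match(names(subtypes$labels)[extreme],
                                     clinical$sample_id)])
chi <- chi_square_2xk(tab)
cat(sprintf("response-by-subtype chi-square: %.3f (df %d), p = %.4f\n",
            chi$statistic, chi$df, chi$p))

emb <- pca_embed(expr, n_components = 3)
cat(sprintf("PCA variance fractions (first three): %s\n",
            paste(round(100 * emb$var_fraction[1:3], 1), collapse = " / ")))
write.table(data.frame(sample_id = rownames(emb$scores), round(emb$scores, 4)),
            file.path(out_dir, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
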