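#!/usr/bin/env Rscript
# Stage 5: signature similarity and co-expression.
#
# Builds the cohort's signature profile (per-gene median log2 expression)
# and ranks the conditions of a compendium by Pearson similarity and the
# relative-similarity index. No public compendium ships with the package, so
# a synthetic compendium is constructed here: a family of conditions with
# known, graded resemblance to the cohort profile (labelled synthetic
# throughout). The co-expression stage extracts the top co-expressed genes
# of CD68 and SMPD1 across the cohort samples and intersects the two lists.

library(ovasig)

out_dir <- "results/similarity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression_tsv("results/preprocess/expression_log2.tsv")
profile <- signature_profile(expr)

# synthetic compendium: graded distortions of the cohort profile plus
# unrelated conditions
set.seed(11)
distort <- function(sdev) profile + rnorm(length(profile), sd = sdev)
profiles <- rbind(
  synthetic_ovarian_like_a = distort(0.3),
  synthetic_ovarian_like_b = distort(0.6),
  synthetic_related_tissue = distort(1.2),
  synthetic_distant_a = rnorm(length(profile), sd = 1.5),
  synthetic_distant_b = rnorm(length(profile), sd = 1.5),
  synthetic_small_n = distort(0.3))
colnames(profiles) <- names(profile)
comp <- compendium(profiles, n_arrays = c(40, 35, 25, 60, 45, 8), n_floor = 15)

ranking <- rank_conditions(profile, comp, top_k = 10)
print(ranking)
write.table(ranking$full, file.path(out_dir, "condition_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("conditions excluded (too few arrays or genes):",
    paste(ranking$excluded, collapse = ", "), "\n")

cx_cd68 <- coexpression_top_n(as.matrix(expr), "CD68", n = 20)
cx_smpd1 <- coexpression_top_n(as.matrix(expr), "SMPD1", n = 20)
ov <- list_overlap(cx_cd68, cx_smpd1)
cat(sprintf("top-20 co-expression lists of CD68 and SMPD1 share %d genes: %s\n",
            ov$count, paste(ov$genes, collapse = ", ")))
write.table(cx_cd68, file.path(out_dir, "coexpression_CD68.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cx_smpd1, file.path(out_dir, "coexpression_SMPD1.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
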