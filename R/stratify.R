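#' Gene-gene Pearson correlation matrix with Holm adjustment
#'
#' Pairwise Pearson correlations between genes on the log2 expression scale,
#' with two-sided t-based p-values and Holm step-down adjustment over the set
#' of unique off-diagonal pairs. Constant genes give undefined correlations,
#' recorded as `NA` with a warning.
#'
#' @param expr a log2-scale [expression_matrix] without missing values and at
#'   least 3 samples.
#' @return A `correlation_result`: list with genes x genes matrices `r`,
#'   `p_raw`, `p_adj`, the per-pair sample size `n_used`, and `genes`.
#' @export
correlation_matrix <- function(expr) {
  if (expr_scale(expr) != "log2") stop("correlations are computed on log2 scale")
  x <- as_plain_matrix(expr)
  if (any(is.na(x))) stop("missing values present; impute first")
  n <- nrow(x)
  if (n < 3) stop("at least 3 samples required")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    warning("constant gene(s), correlations undefined: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  r <- suppressWarnings(cor(x))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  diag(r) <- ifelse(sds == 0, NA, 1)
  diag(p) <- ifelse(sds == 0, NA, 0) # self-correlation: r = 1, p = 0 convention
  up <- upper.tri(p)
  p_adj <- p
  p_adj[up] <- p.adjust(p[up], method = "holm")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(r = r, p_raw = p, p_adj = p_adj,
                 n_used = matrix(n, ncol(x), ncol(x),
                                 dimnames = dimnames(r)),
                 genes = colnames(x)),
            class = "correlation_result")
}

#' Agglomerative hierarchical clustering (UPGMA)
#'
#' Average-linkage (UPGMA) agglomeration under either the Euclidean distance
#' or the uncentered-Pearson dissimilarity
#' \eqn{d(x, y) = 1 - \sum x_i y_i / (\|x\| \|y\|)}. Average linkage is the
#' unweighted mean pairwise dissimilarity between clusters. When several
#' merges tie at the minimal dissimilarity, the pair whose clusters contain
#' the smallest original row indices (lexicographically) is merged first.
#'
#' @param x numeric matrix; rows are the items to cluster.
#' @param metric `"euclidean"` or `"pearson_uncentered"`.
#' @param linkage only `"average"` is provided.
#' @return An `ova_hclust` object (fields `merge`, `height`, `order`,
#'   `labels`, `metric`, `linkage`), convertible with [as.hclust()].
#' @export
hcluster <- function(x, metric = c("euclidean", "pearson_uncentered"),
                     linkage = "average") {
  metric <- match.arg(metric)
  if (linkage != "average") stop("only average linkage (UPGMA) is provided")
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("at least 2 items required")
  labels <- rownames(x) %||% as.character(seq_len(n))
  if (metric == "euclidean") {
    d <- as.matrix(dist(x, method = "euclidean"))
  } else {
    norms <- sqrt(rowSums(x^2))
    zero <- which(norms == 0)
    if (length(zero))
      stop("zero-norm row(s) under uncentered Pearson: ",
           paste(labels[zero], collapse = ", "))
    u <- (x %*% t(x)) / outer(norms, norms)
    d <- 1 - u
    diag(d) <- 0
  }

  # active cluster bookkeeping; inactive rows/columns are parked at Inf
  size <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negative = singleton
  minleaf <- seq_len(n)          # smallest original index, for tie-breaking
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  diag(d) <- Inf

  for (step in seq_len(n - 1)) {
    md <- min(d)
    cand <- which(d <= md + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # among ties, merge the pair with lexicographically smallest leaf indices
    lex1 <- pmin(minleaf[cand[, 1]], minleaf[cand[, 2]])
    lex2 <- pmax(minleaf[cand[, 1]], minleaf[cand[, 2]])
    pick <- order(lex1, lex2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    merge[step, ] <- sort(c(id[i], id[j])) # hclust merge-row ordering
    height[step] <- d[i, j]
    # Lance-Williams update for UPGMA
    newd <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- newd
    d[, i] <- newd
    d[i, i] <- Inf
    d[j, ] <- Inf
    d[, j] <- Inf
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
  }

  structure(list(merge = merge, height = height,
                 order = dendrogram_order(merge),
                 labels = labels, metric = metric, linkage = linkage,
                 n = n),
            class = "ova_hclust")
}

# leaf order by left-to-right traversal of the merge tree
dendrogram_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
as.hclust.ova_hclust <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = x$linkage,
                 call = match.call(), dist.method = x$metric),
            class = "hclust")
}

#' @export
print.ova_hclust <- function(x, ...) {
  cat(sprintf("UPGMA clustering of %d items (%s metric)\n", x$n, x$metric))
  invisible(x)
}

#' Cut a dendrogram into k groups
#'
#' Breaks the `k - 1` largest-height merges (for average linkage on a proper
#' dissimilarity heights are monotone, so this equals the standard cut).
#'
#' @param tree an `ova_hclust`.
#' @param k number of groups.
#' @return Integer group membership named by item labels.
#' @export
cut_dendrogram <- function(tree, k) {
  if (k > tree$n) stop("k exceeds the number of items")
  stats::cutree(as.hclust(tree), k = k)
}

#' Immune-low / immune-high / mixed subtype assignment
#'
#' Clusters patients by UPGMA on the uncentered-Pearson dissimilarity over
#' the full signature, cuts the dendrogram into `k` clusters, ranks clusters
#' by their mean expression over the immune-core genes, and labels the
#' lowest-ranking cluster `immune_low`, the highest `immune_high`, and all
#' others `mixed`. If the spread between the extreme cluster means is below
#' `min_separation`, no immune structure is claimed and every sample is
#' labelled `mixed`.
#'
#' @param expr a log2-scale [expression_matrix] without missing values.
#' @param signature a [gene_signature]; its genes are used for clustering.
#' @param k number of dendrogram clusters.
#' @param min_separation minimum difference (log2 units) between the highest
#'   and lowest cluster mean immune-core expression for low/high labels to be
#'   assigned. The default (2) exceeds the spread that correlated immune-core
#'   noise alone produces between clusters, so cohorts without planted
#'   structure come back all-mixed.
#' @param core_genes genes whose mean ranks the clusters; defaults to the 8
#'   immune markers plus S1PR4 and CD1B.
#' @return A `subtype_assignment`: list with `labels` (factor per sample),
#'   `cluster` (integer membership), `cluster_core_means`, `core_genes`,
#'   `k`, `min_separation`, and the `tree`.
#' @export
assign_subtypes <- function(expr, signature = default_signature(), k = 3,
                            min_separation = 2,
                            core_genes = immune_core_genes(signature)) {
  x <- as_plain_matrix(expr)
  if (any(is.na(x))) stop("missing values present; impute first")
  sig_genes <- intersect(signature$genes$symbol, colnames(x))
  core <- intersect(core_genes, colnames(x))
  if (!length(core))
    stop("none of the immune-core genes are present in the matrix")
  if (k > nrow(x)) stop("k exceeds the number of samples")
  xs <- x[, sig_genes, drop = FALSE]
  tree <- hcluster(xs, metric = "pearson_uncentered")
  cluster <- cut_dendrogram(tree, k)
  core_mean <- tapply(rowMeans(x[, core, drop = FALSE]), cluster, mean)
  lab <- rep("mixed", length(cluster))
  if (max(core_mean) - min(core_mean) >= min_separation) {
    lab[cluster == names(core_mean)[which.min(core_mean)]] <- "immune_low"
    lab[cluster == names(core_mean)[which.max(core_mean)]] <- "immune_high"
  }
  labels <- factor(lab, levels = c("immune_low", "mixed", "immune_high"))
  names(labels) <- rownames(x)
  structure(list(labels = labels, cluster = cluster,
                 cluster_core_means = core_mean, core_genes = core,
                 k = k, min_separation = min_separation, tree = tree),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  print(table(x$labels))
  invisible(x)
}

# Levene's test with center = mean: one-way ANOVA of absolute deviations
# from the group means.
levene_p <- function(values, groups) {
  z <- abs(values - ave(values, groups))
  if (all(z == z[1])) return(1)
  anova(lm(z ~ groups))[["Pr(>F)"]][1]
}

# Games-Howell post hoc: pairwise Welch t statistics referred to the
# studentized-range distribution.
games_howell <- function(values, groups) {
  gl <- levels(groups)
  k <- length(gl)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  vs <- tapply(values, groups, var)
  out <- NULL
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    se2 <- vs[a] / ns[a] + vs[b] / ns[b]
    t <- (ms[a] - ms[b]) / sqrt(se2)
    df <- se2^2 / ((vs[a] / ns[a])^2 / (ns[a] - 1) +
                   (vs[b] / ns[b])^2 / (ns[b] - 1))
    p <- ptukey(abs(t) * sqrt(2), nmeans = k, df = df, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = gl[a], group2 = gl[b],
                                 diff = unname(ms[a] - ms[b]),
                                 t = unname(t), df = unname(df),
                                 p = unname(p)))
  }
  out
}

#' Per-gene group comparison with variance-guided test routing
#'
#' For each gene, Levene's test (center = mean, alpha = 0.05) decides the
#' variance assumption; two groups are then compared by Student's t
#' (equal variances) or Welch's t, and three or more groups by one-way ANOVA
#' with Tukey HSD or Welch's ANOVA with Games-Howell post hoc. All p-values
#' are two-sided; Holm-adjusted p-values over genes are reported alongside.
#'
#' @param expr a log2-scale [expression_matrix] without missing values.
#' @param labels grouping of samples (factor or coercible); at least 2
#'   groups of at least 2 samples.
#' @param levene_alpha significance level of the variance-equality gate.
#' @return A `group_comparison`: list with `table` (per-gene data frame:
#'   group means, `levene_p`, `test`, `statistic`, `p_raw`, `p_holm`,
#'   `direction` = group with the highest mean) and `posthoc` (per-gene
#'   pairwise results for 3+ groups).
#' @export
compare_groups <- function(expr, labels, levene_alpha = 0.05) {
  x <- as_plain_matrix(expr)
  if (any(is.na(x))) stop("missing values present; impute first")
  groups <- droplevels(as.factor(labels))
  if (length(groups) != nrow(x)) stop("labels must match the sample count")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least 2 groups required")
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  gl <- levels(groups)
  k <- length(gl)
  posthoc <- list()
  rows <- lapply(colnames(x), function(g) {
    v <- x[, g]
    means <- tapply(v, groups, mean)
    if (any(tapply(v, groups, function(z) length(unique(z))) < 1) ||
        all(v == v[1])) {
      # identical values everywhere: no variance to test against
      return(data.frame(gene = g, t(setNames(means, paste0("mean_", gl))),
                        levene_p = 1, test = if (k == 2) "student_t"
                                            else "anova_tukey",
                        statistic = 0, p_raw = 1,
                        direction = gl[which.max(means)],
                        stringsAsFactors = FALSE))
    }
    lp <- levene_p(v, groups)
    equal_var <- lp >= levene_alpha
    if (k == 2) {
      tt <- t.test(v ~ groups, var.equal = equal_var)
      test <- if (equal_var) "student_t" else "welch_t"
      stat <- unname(tt$statistic)
      p <- tt$p.value
    } else {
      ow <- oneway.test(v ~ groups, var.equal = equal_var)
      test <- if (equal_var) "anova_tukey" else "welch_anova_games_howell"
      stat <- unname(ow$statistic)
      p <- ow$p.value
      posthoc[[g]] <<- if (equal_var) {
        th <- TukeyHSD(aov(v ~ groups))$groups
        data.frame(contrast = rownames(th), diff = th[, "diff"],
                   p = th[, "p adj"], row.names = NULL)
      } else {
        gh <- games_howell(v, groups)
        data.frame(contrast = paste(gh$group2, gh$group1, sep = "-"),
                   diff = -gh$diff, p = gh$p, row.names = NULL)
      }
    }
    data.frame(gene = g, t(setNames(means, paste0("mean_", gl))),
               levene_p = lp, test = test, statistic = stat, p_raw = p,
               direction = gl[which.max(means)], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- p.adjust(tab$p_raw, method = "holm")
  structure(list(table = tab, posthoc = posthoc, groups = gl),
            class = "group_comparison")
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson's chi-square without continuity correction,
#' df = (r - 1)(c - 1).
#'
#' @param table matrix of non-negative integer counts with no zero row or
#'   column margin.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_2xk <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Principal component embedding of samples
#'
#' Column-centered SVD of the expression matrix, optionally restricted to
#' genes whose group-comparison p-value passes a cutoff (the usual
#' "significant genes only" PCA view).
#'
#' @param expr a log2-scale [expression_matrix] without missing values.
#' @param n_components number of components to return.
#' @param prefilter_p optional p-value cutoff; requires `labels`.
#' @param labels grouping used for the prefilter.
#' @return List with `scores` (samples x components), `var_fraction`
#'   (explained variance fractions over all components), `genes_used`.
#' @export
pca_embed <- function(expr, n_components = 3, prefilter_p = NULL,
                      labels = NULL) {
  x <- as_plain_matrix(expr)
  if (any(is.na(x))) stop("missing values present; impute first")
  genes <- colnames(x)
  if (!is.null(prefilter_p)) {
    if (is.null(labels)) stop("prefilter_p requires group labels")
    cmp <- compare_groups(expression_matrix(x, "log2"), labels)
    genes <- cmp$table$gene[cmp$table$p_raw < prefilter_p]
    if (length(genes) < n_components)
      stop("prefilter leaves fewer genes than components")
    x <- x[, genes, drop = FALSE]
  }
  if (n_components > min(dim(x)))
    stop("n_components exceeds matrix rank bound")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores[, seq_len(n_components), drop = FALSE],
       var_fraction = sv$d^2 / sum(sv$d^2),
       genes_used = genes)
}
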