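test_that("correlation matrix matches the direct formula", {
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("s", 1:5), c("a", "b", "c")))
  res <- correlation_matrix(expression_matrix(x, "log2"))
  for (i in 1:3) for (j in 1:3) {
    num <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j])))
    den <- sqrt(sum((x[, i] - mean(x[, i]))^2) * sum((x[, j] - mean(x[, j]))^2))
    expect_lt(abs(res$r[i, j] - num / den), 1e-12)
  }
  # self-correlation convention
  expect_equal(unname(diag(res$r)), rep(1, 3))
  expect_equal(unname(diag(res$p_raw)), rep(0, 3))
  # Holm adjustment over the unique off-diagonal pairs
  up <- upper.tri(res$p_raw)
  expect_equal(res$p_adj[up], p.adjust(res$p_raw[up], "holm"))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
})

test_that("constant genes give flagged undefined correlations", {
  x <- cbind(a = rnorm(6), b = rep(1, 6))
  rownames(x) <- paste0("s", 1:6)
  expect_warning(res <- correlation_matrix(expression_matrix(x, "log2")), "b")
  expect_true(is.na(res$r["a", "b"]))
})

test_that("UPGMA handles degenerate geometry as documented", {
  x <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1))
  tr <- hcluster(x, metric = "pearson_uncentered")
  expect_equal(tr$height[1], 0)          # identical rows merge at height 0
  expect_equal(tr$height[2], 1)          # orthogonal vectors: u = 0, d = 1
  expect_error(hcluster(rbind(a = c(0, 0), b = c(1, 0)),
                        metric = "pearson_uncentered"), "a")
})

test_that("merge sequences equal the brute-force agglomeration oracle", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:8, 1)
    x <- matrix(rnorm(n * 4), n, 4)
    rownames(x) <- paste0("r", seq_len(n))
    metric <- if (s %% 2) "euclidean" else "pearson_uncentered"
    tr <- hcluster(x, metric = metric)
    d0 <- if (metric == "euclidean") as.matrix(dist(x)) else {
      nr <- sqrt(rowSums(x^2))
      1 - (x %*% t(x)) / outer(nr, nr)
    }
    diag(d0) <- 0
    or <- oracle_upgma(d0)
    expect_identical(tr$merge, or$merge)
    expect_equal(tr$height, or$height, tolerance = 1e-10)
  }
})

test_that("UPGMA agrees with stats::hclust on tie-free euclidean data", {
  set.seed(9)
  x <- matrix(rnorm(60), 12, 5)
  rownames(x) <- paste0("r", 1:12)
  tr <- as.hclust(hcluster(x, metric = "euclidean"))
  ref <- hclust(dist(x), method = "average")
  expect_equal(sort(tr$height), sort(ref$height), tolerance = 1e-10)
  for (k in c(2, 4, 6)) {
    tab <- table(stats::cutree(tr, k), stats::cutree(ref, k))
    expect_true(all(rowSums(tab > 0) == 1))  # identical partitions
  }
})

test_that("heights are non-decreasing along UPGMA merges", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- matrix(rnorm(80), 16, 5)
    tr <- hcluster(x, metric = "euclidean")
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("subtype labels are invariant to sample order", {
  co <- generate_cohort(synthetic_config(n_samples = 50, seed = 3))
  st1 <- assign_subtypes(co$expression, co$signature)
  perm <- sample(nrow(co$expression))
  xp <- expression_matrix(as.matrix(co$expression)[perm, ], "log2")
  st2 <- assign_subtypes(xp, co$signature)
  ids <- rownames(co$expression)
  expect_identical(as.character(st1$labels[ids]), as.character(st2$labels[ids]))
})

test_that("the separation guard labels everything mixed when clusters are close", {
  # three clear positional clusters whose immune-core means differ by ~0.3
  set.seed(4)
  core <- immune_core_genes()
  genes <- default_signature()$genes$symbol
  x <- matrix(rnorm(30 * length(genes), sd = 0.05), 30, length(genes),
              dimnames = list(paste0("s", 1:30), genes))
  x[, core] <- x[, core] + rep(c(0, 0.15, 0.3), each = 10)
  st <- assign_subtypes(expression_matrix(x + 5, "log2"), min_separation = 0.5)
  expect_true(all(st$labels == "mixed"))
  # with a permissive threshold the same data yields low/high labels
  st2 <- assign_subtypes(expression_matrix(x + 5, "log2"), min_separation = 0.05)
  expect_true(any(st2$labels == "immune_low") && any(st2$labels == "immune_high"))
  # ranking contract: the high cluster mean exceeds the low cluster mean
  expect_gt(max(st2$cluster_core_means), min(st2$cluster_core_means))
})

test_that("group comparison handles identical groups and routes by variance", {
  x <- cbind(g1 = c(1, 2, 3, 1, 2, 3))
  rownames(x) <- paste0("s", 1:6)
  cmp <- compare_groups(expression_matrix(x, "log2"),
                        rep(c("A", "B"), each = 3))
  expect_equal(cmp$table$statistic, 0)
  expect_equal(cmp$table$p_raw, 1)
})

test_that("a two-SD shift is detected after Holm correction in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    x <- cbind(shifted = c(rnorm(50), rnorm(50, 2)),
               nullg = rnorm(100))
    rownames(x) <- paste0("s", 1:100)
    cmp <- compare_groups(expression_matrix(x, "log2"),
                          rep(c("A", "B"), each = 50))
    if (cmp$table$p_holm[cmp$table$gene == "shifted"] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("unequal variances route to the Welch branch", {
  welch <- 0L
  for (s in 1:20) {
    set.seed(s)
    x <- cbind(g = c(rnorm(30, sd = 1), rnorm(30, sd = 3)))
    rownames(x) <- paste0("s", 1:60)
    cmp <- compare_groups(expression_matrix(x, "log2"),
                          rep(c("A", "B"), each = 30))
    if (cmp$table$test == "welch_t") welch <- welch + 1L
  }
  expect_gte(welch, 18L)
})

test_that("three-group comparisons attach the matching post hoc test", {
  set.seed(2)
  x <- cbind(g = c(rnorm(20), rnorm(20, 1), rnorm(20, 2)))
  rownames(x) <- paste0("s", 1:60)
  labels <- rep(c("lo", "mid", "hi"), each = 20)
  cmp <- compare_groups(expression_matrix(x, "log2"), labels)
  expect_true(cmp$table$test %in% c("anova_tukey", "welch_anova_games_howell"))
  expect_true(!is.null(cmp$posthoc$g))
  expect_equal(nrow(cmp$posthoc$g), 3)   # three pairwise contrasts
  expect_true(all(cmp$posthoc$g$p >= 0 & cmp$posthoc$g$p <= 1))
})

test_that("the mean-centred Levene gate matches car::leveneTest", {
  library(car)
  set.seed(11)
  v <- c(rnorm(25, sd = 1), rnorm(25, sd = 2.5))
  g <- factor(rep(c("A", "B"), each = 25))
  ours <- ovasig:::levene_p(v, g)
  ref <- car::leveneTest(v, g, center = mean)[["Pr(>F)"]][1]
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("chi-square follows the textbook Pearson statistic", {
  res <- chi_square_2xk(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(round(res$statistic, 3), 6.667)
  expect_equal(res$df, 1)
  # perfectly proportional table
  res2 <- chi_square_2xk(matrix(c(10, 20, 20, 40), 2, 2))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  # 2 x 3 table
  expect_equal(chi_square_2xk(matrix(1:6, 2, 3))$df, 2)
  expect_error(chi_square_2xk(matrix(c(0, 0, 1, 2), 2, 2)), "margin")
})

test_that("PCA embedding matches an eigendecomposition oracle", {
  set.seed(6)
  x <- matrix(rnorm(24), 6, 4, dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
  emb <- pca_embed(expression_matrix(x, "log2"), n_components = 3)
  expect_true(all(emb$var_fraction >= 0))
  expect_equal(sum(emb$var_fraction), 1, tolerance = 1e-12)
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(xc) * (nrow(x) - 1), symmetric = TRUE)
  for (k in 1:3) {
    proj <- xc %*% ev$vectors[, k]
    expect_lt(min(max(abs(emb$scores[, k] - proj)),
                  max(abs(emb$scores[, k] + proj))), 1e-9)
  }
  # rank-1 matrix: first component carries all the variance
  r1 <- outer(1:6, c(1, 2, 3, 4)) + 0
  dimnames(r1) <- dimnames(x)
  emb1 <- pca_embed(expression_matrix(r1, "log2"), n_components = 1)
  expect_equal(emb1$var_fraction[1], 1, tolerance = 1e-12)
  expect_error(pca_embed(expression_matrix(x, "log2"), n_components = 7),
               "n_components")
})
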