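hkg <- c("ACTB", "TOP1", "UBC", "YWHAZ")

make_ct <- function(ct_g1_s1 = 20, hkg_s1 = 18, ct_g1_cal = 22, hkg_cal = 18) {
  m <- rbind(S1 = c(g1 = ct_g1_s1, setNames(rep(hkg_s1, 4), hkg)),
             CAL = c(g1 = ct_g1_cal, setNames(rep(hkg_cal, 4), hkg)))
  ct_table(m, hkg_genes = hkg, calibrator_id = "CAL")
}

test_that("delta-delta-Ct normalization reproduces hand arithmetic", {
  # ddCt = (20 - 18) - (22 - 18) = -2  ->  R = 2^2 = 4
  expr <- normalize_qpcr(make_ct())
  expect_equal(unname(expr["S1", "g1"]), 4)
  # calibrator sample maps to R = 1 for every gene
  expect_equal(unname(expr["CAL", "g1"]), 1)
  # sample with Ct identical to the calibrator -> R = 1
  expr2 <- normalize_qpcr(make_ct(ct_g1_s1 = 22))
  expect_equal(unname(expr2["S1", "g1"]), 1)
})

test_that("normalization is invariant to a per-sample Ct offset", {
  base <- normalize_qpcr(make_ct())
  shifted <- normalize_qpcr(make_ct(ct_g1_s1 = 20 + 3.7, hkg_s1 = 18 + 3.7))
  expect_equal(shifted["S1", "g1"], base["S1", "g1"], tolerance = 1e-12)
})

test_that("normalization flags missing calibrator and HKG values", {
  m <- rbind(S1 = c(g1 = 20, setNames(rep(18, 4), hkg)),
             CAL = c(g1 = NA, setNames(rep(18, 4), hkg)))
  expect_error(normalize_qpcr(ct_table(m, hkg, "CAL")), "g1")
  m2 <- rbind(S1 = c(g1 = 20, setNames(c(NA, 18, 18, 18), hkg)),
              CAL = c(g1 = 22, setNames(rep(18, 4), hkg)))
  expect_warning(out <- normalize_qpcr(ct_table(m2, hkg, "CAL")), "S1")
  expect_true(is.na(out["S1", "g1"]))
})

test_that("log2 transform enforces its scale and positivity contracts", {
  lin <- expression_matrix(matrix(c(1, 4), 2, 1,
                                  dimnames = list(c("a", "b"), "g")),
                           scale = "linear")
  lg <- log2_transform(lin)
  expect_equal(unname(lg[, 1]), c(0, 2))
  expect_identical(expr_scale(lg), "log2")
  expect_error(log2_transform(lg), "already")
  expect_error(expression_matrix(matrix(-1, 1, 1,
                                        dimnames = list("a", "g")), "linear"),
               "positive")
})

test_that("chained-equations imputation leaves complete data untouched", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("g", 1:4)))
  em <- expression_matrix(x, "log2")
  expect_identical(impute_chained(em), em)
})

test_that("imputation recovers a perfect linear relation up to donor spacing", {
  set.seed(42)
  x1 <- rnorm(30)
  x <- cbind(g1 = x1, g2 = 2 * x1 + 1, g3 = rnorm(30))
  rownames(x) <- paste0("s", 1:30)
  truth <- x[5, "g2"]
  x[5, "g2"] <- NA
  out <- impute_chained(expression_matrix(x, "log2"), seed = 3)
  # PMM draws an observed donor value, so the error is bounded by the gap
  # between the truth and its nearest observed neighbours
  gaps <- sort(abs(x[-5, "g2"] - truth))[1:5]
  expect_lte(abs(out[5, "g2"] - truth), max(gaps) + 1e-12)
  # observed cells unchanged, nothing left missing
  expect_identical(out[-5, ], expression_matrix(x, "log2")[-5, ])
  expect_false(anyNA(out))
})

test_that("imputation is deterministic given the seed", {
  set.seed(7)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
  em <- inject_missing(expression_matrix(x, "log2"), 0.1, seed = 2)
  a <- impute_chained(em, seed = 9)
  b <- impute_chained(em, seed = 9)
  expect_identical(a, b)
})

test_that("chained imputation beats column-mean imputation under correlation", {
  wins <- 0L
  for (s in 1:20) {
    cfg <- synthetic_config(
      n_samples = 80,
      gene_blocks = list(list(name = "b", genes = paste0("g", 1:12),
                              rho = 0.7, shift = c(0, 0, 0))),
      noise_sd = 0,
      beta_true_survival = setNames(numeric(0), character(0)),
      beta_true_response = setNames(numeric(0), character(0)),
      seed = s)
    truth <- generate_cohort(cfg)$expression
    holey <- inject_missing(truth, 0.1, seed = s + 1000)
    mask <- is.na(holey)
    imp <- impute_chained(holey, seed = s)
    colmeans <- holey
    for (j in seq_len(ncol(colmeans)))
      colmeans[is.na(colmeans[, j]), j] <- mean(colmeans[, j], na.rm = TRUE)
    rmse <- function(m) sqrt(mean((m[mask] - truth[mask])^2))
    if (rmse(imp) < rmse(colmeans)) wins <- wins + 1L
  }
  expect_gte(wins, 18L)
})

test_that("imputation rejects degenerate missingness patterns", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("a", "b")))
  x[, 2] <- NA
  expect_error(impute_chained(expression_matrix(x, "log2")), "entirely missing")
  x[, 2] <- rnorm(10)
  x[1:6, 2] <- NA
  expect_error(impute_chained(expression_matrix(x, "log2")), "half missing")
})
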