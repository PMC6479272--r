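test_that("concordance follows its conventions on degenerate inputs", {
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(c_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 0)
  expect_equal(c_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_error(c_index(c(1, 2), c(5, 5), c(1, 1)), "usable")
})

test_that("concordance equals the brute-force pair oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(10:25, 1)
    eta <- sample(seq(-1, 1, length.out = 7), n, replace = TRUE) # forces ties
    time <- sample(1:12, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0 || length(unique(time)) < 2) next
    expect_identical(c_index(eta, time, event),
                     oracle_cindex(eta, time, event))
  }
})

test_that("explained variation equals the longhand oracle implementation", {
  for (s in 1:6) {
    d <- make_surv(40, 2, beta = c(0.8, 0), seed = 700 + s)
    eta <- as.vector(d$X %*% c(1, 0.2))
    expect_equal(pev(eta, d$time, d$event),
                 oracle_pev(eta, d$time, d$event), tolerance = 1e-10)
  }
})

test_that("explained variation behaves at its boundaries", {
  d <- make_surv(60, 1, beta = 1, seed = 44)
  expect_warning(v0 <- pev(rep(1, 60), d$time, d$event), "constant")
  expect_identical(v0, 0)
  # invariant to linear rescaling of the predictor
  eta <- d$X[, 1]
  expect_equal(pev(eta, d$time, d$event), pev(2 * eta + 3, d$time, d$event),
               tolerance = 1e-10)
  # bounded in the planted-signal battery
  for (s in 1:5) {
    dd <- make_surv(100, 1, beta = runif(1, 0.5, 1.5), seed = 800 + s)
    v <- pev(dd$X[, 1], dd$time, dd$event)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("global p follows the constant-predictor convention", {
  d <- make_surv(30, 1, seed = 2)
  expect_warning(p <- global_p(rep(0.5, 30), d$time, d$event), "constant")
  expect_identical(p, 1)
})

test_that("added-value testing handles duplicate and informative predictors", {
  d <- make_surv(80, 2, beta = c(1, 0), seed = 3)
  eta_c <- as.vector(d$X %*% c(1, 0))
  # exact duplicate carries no added value; collinearity branch engages
  expect_warning(p_dup <- added_value_test(eta_c, eta_c, d$time, d$event),
                 "collinear")
  expect_equal(p_dup, 1)
  # an independent noise predictor should rarely look valuable
  set.seed(10)
  p_noise <- added_value_test(eta_c, rnorm(80), d$time, d$event)
  expect_gte(p_noise, 0)
  expect_lte(p_noise, 1)
})

test_that("added value detects an omics-only signal", {
  hits <- 0L
  for (s in 1:10) {
    d <- make_surv(200, 2, beta = c(0, 1.2), scale = 30, seed = 900 + s)
    eta_clin <- d$X[, 1] * 0.01 + rnorm(200, sd = 0.1) # clinically null
    eta_omics <- d$X[, 2]
    if (added_value_test(eta_clin, eta_omics, d$time, d$event) < 0.01)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("quartile risk groups reproduce the hand-computed log-rank toy", {
  # groups A = {1, 2} and B = {3, 4}, all events: chisq = 49/17
  eta <- c(2, 2, 1, 1)
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  lr <- survival::survdiff(survival::Surv(time, event) ~ factor(eta))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-3)
  expect_equal(round(49 / 17, 3), 2.882)
})

test_that("risk stratification follows the strict quantile rule", {
  set.seed(5)
  eta <- c(1:12) / 10
  d <- make_surv(12, 1, seed = 5)
  rs <- risk_groups_km(eta, d$time, d$event)
  q <- quantile(eta, c(0.25, 0.75), type = 7)
  expect_true(all(eta[rs$group == "low"] < q[1]))
  expect_true(all(eta[rs$group == "high"] > q[2]))
  # boundary values (equal to a threshold) stay intermediate
  eta2 <- c(rep(1, 3), rep(2, 6), rep(3, 3))
  rs2 <- risk_groups_km(eta2, d$time, d$event)
  expect_true(all(rs2$group[eta2 == quantile(eta2, 0.25)] != "low"))
})

test_that("identical survival in all groups gives a zero log-rank statistic", {
  # quartile thresholds put 3 / 6 / 3 subjects into the groups, and every
  # group carries the same survival experience {1, 2, 3}, all events
  eta <- c(rep(0, 3), rep(1, 6), rep(2, 3))
  time <- c(1, 2, 3, 1, 1, 2, 2, 3, 3, 1, 2, 3)
  event <- rep(1, 12)
  rs <- risk_groups_km(eta, time, event)
  expect_equal(as.vector(table(rs$group)), c(3, 6, 3))
  expect_lt(rs$logrank$chisq, 1e-10)
})

test_that("Kaplan-Meier without censoring equals the empirical survival", {
  # eta 0..1 over 8 subjects: intermediate group = subjects 3..6
  rs <- risk_groups_km(seq(0, 1, length.out = 8), 1:8, rep(1, 8))
  km <- rs$km$intermediate
  expect_equal(km$time, 3:6)
  emp <- sapply(3:6, function(t) mean(3:6 > t))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("outer LOO predictors are deterministic and order-invariant", {
  d <- make_surv(30, 3, beta = c(1, 0, 0), scale = 30, seed = 6)
  rownames(d$X) <- paste0("s", 1:30)
  cv1 <- loocv_predictors(d$X, d$time, d$event, "ridge")
  perm <- sample(30)
  cv2 <- loocv_predictors(d$X[perm, ], d$time[perm], d$event[perm], "ridge")
  expect_equal(cv1$eta[paste0("s", 1:30)], cv2$eta[paste0("s", 1:30)],
               tolerance = 1e-10)
})

test_that("shuffling the outcome destroys cross-validated concordance", {
  d <- make_surv(40, 3, beta = c(1.2, 0, 0), scale = 30, seed = 7)
  cv <- loocv_predictors(d$X, d$time, d$event, "ridge")
  ci_true <- c_index(cv$eta, d$time, d$event)
  set.seed(1)
  perm <- sample(40)
  ci_shuf <- c_index(cv$eta, d$time[perm], d$event[perm])
  expect_gt(ci_true, 0.6)
  expect_lt(abs(ci_shuf - 0.5), 0.15)
})

test_that("repeated k-fold response validation is reproducible and calibrated", {
  set.seed(20)
  X <- matrix(rnorm(120 * 5), 120, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rbinom(120, 1, 0.5)
  r1 <- repeated_kfold_response(X, y, "ridge", k = 5, repeats = 4, seed = 3)
  r2 <- repeated_kfold_response(X, y, "ridge", k = 5, repeats = 4, seed = 3)
  expect_identical(r1$auc, r2$auc)
  expect_gt(r1$summary["auc_mean"], 0.40)
  expect_lt(r1$summary["auc_mean"], 0.60)
})

test_that("repeated k-fold detects a planted response signal", {
  set.seed(21)
  X <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- rbinom(200, 1, plogis(X[, 1] + X[, 2] + X[, 3]))
  r <- repeated_kfold_response(X, y, "ridge", k = 5, repeats = 4, seed = 5,
                               X_reference = X[, 5:6])
  expect_gte(unname(r$summary["auc_mean"]), 0.70)
  expect_lt(unname(r$summary["added_value_p_median"]), 0.05)
})

test_that("performance reports assemble all validation metrics", {
  d <- make_surv(40, 2, beta = c(1, 0), scale = 30, seed = 9)
  eta <- d$X[, 1]
  rep_ <- performance_report(eta, d$time, d$event)
  expect_true(is.finite(rep_$pev))
  expect_true(rep_$c_index > 0.5)
  expect_lt(rep_$global_p, 0.05)
  expect_true(is.na(rep_$added_value_p))
})
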