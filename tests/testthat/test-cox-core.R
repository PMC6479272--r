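test_that("univariate Cox reproduces the analytic three-subject solution", {
  # score equation solved in closed form: u^2 = 1/2, beta = -log(2)/2
  res <- cox_univariate(c(1, 0, 1), c(1, 2, 3), c(1, 1, 1))
  expect_lt(abs(res$beta - (-log(2) / 2)), 1e-6)
  expect_lt(abs(res$hr - 2^(-1 / 2)), 1e-6)
  expect_true(res$converged)
})

test_that("univariate Cox is invariant to covariate rescaling", {
  d <- make_surv(60, 1, beta = 0.5, seed = 3)
  a <- cox_univariate(d$X[, 1], d$time, d$event)
  b <- cox_univariate(2 * d$X[, 1], d$time, d$event)
  expect_equal(b$beta, a$beta / 2, tolerance = 1e-8)
  expect_equal(b$p, a$p, tolerance = 1e-8)
})

test_that("Breslow baseline cumulative hazard matches hand summation", {
  bh <- breslow_cumhaz(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0))
  expect_equal(bh$cumhaz, c(1 / 3, 5 / 6, 11 / 6), tolerance = 1e-12)
  expect_lt(abs(exp(-bh$cumhaz[3]) - exp(-11 / 6)), 1e-9)
})

test_that("penalized Cox at lambda = 0 matches the unpenalized coxph fit", {
  d <- make_surv(70, 4, beta = c(0.5, -0.3, 0, 0), seed = 5)
  ref <- coxph(survival::Surv(d$time, d$event) ~ d$X, ties = "breslow")
  for (pen in c("ridge", "lasso")) {
    fit <- cox_penalized(d$X, d$time, d$event, pen, lambda = 0)
    expect_lt(max(abs(fit$beta - coef(ref))), 1e-6)
    expect_true(fit$converged)
  }
})

test_that("the engine agrees with the Nelder-Mead optimizer oracle", {
  for (s in 1:20) {
    p <- sample(2:3, 1)
    d <- make_surv(30, p, beta = runif(p, -1, 1), seed = 200 + s)
    fit <- cox_penalized(d$X, d$time, d$event, "ridge", lambda = 0.05)
    std <- standardize_columns(d$X)
    obj <- function(b) {
      -oracle_cox_loglik(b, std$X, d$time, d$event) / nrow(d$X) +
        0.05 * sum(b^2) / 2
    }
    opt <- optim(rep(0, p), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    expect_lt(max(abs(fit$beta_std - opt$par)), 1e-5)
  }
})

test_that("lasso at lambda >= lambda_max returns the empty model", {
  d <- make_surv(50, 5, beta = c(1, 0, 0, 0, 0), seed = 9)
  std <- standardize_columns(d$X)
  lmax <- lambda_grid(std$X, d$time, d$event, "lasso")[1]
  fit <- cox_penalized(d$X, d$time, d$event, "lasso", lambda = lmax * 1.0001)
  expect_true(all(fit$beta_std == 0))
  expect_setequal(fit$excluded, colnames(d$X))
})

test_that("ridge coefficient norms shrink monotonically in lambda", {
  for (s in 1:5) {
    d <- make_surv(40, 3, beta = runif(3, -1, 1), seed = 300 + s)
    lams <- c(0.01, 0.1, 1, 10)
    norms <- sapply(lams, function(l)
      sqrt(sum(cox_penalized(d$X, d$time, d$event, "ridge", l)$beta_std^2)))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("ridge and lasso paths agree with glmnet at matched lambdas", {
  library(glmnet)
  d <- make_surv(80, 5, beta = c(0.8, -0.5, 0.3, 0, 0), seed = 12)
  std <- standardize_columns(d$X)
  lams <- exp(seq(log(0.5), log(0.005), length.out = 25))
  for (alpha in c(0, 1)) {
    gf <- glmnet(std$X, survival::Surv(d$time, d$event), family = "cox",
                 alpha = alpha, lambda = lams, standardize = FALSE,
                 thresh = 1e-12)
    mine <- sapply(lams, function(l)
      cox_penalized(d$X, d$time, d$event,
                    if (alpha == 0) "ridge" else "lasso", l)$beta_std)
    expect_lt(max(abs(mine - as.matrix(gf$beta))), 1e-4)
  }
})

test_that("standardization invariance holds for penalized fits", {
  d <- make_surv(60, 3, beta = c(0.6, -0.4, 0), seed = 17)
  fit1 <- cox_penalized(d$X, d$time, d$event, "ridge", lambda = 0.2)
  X2 <- d$X
  X2[, 2] <- X2[, 2] * 10
  fit2 <- cox_penalized(X2, d$time, d$event, "ridge", lambda = 0.2)
  expect_equal(fit2$beta_std, fit1$beta_std, tolerance = 1e-8)
  expect_equal(fit2$beta[2], fit1$beta[2] / 10, tolerance = 1e-8)
  expect_equal(fit2$eta, fit1$eta, tolerance = 1e-8)
})

test_that("LOO-CV lambda selection is internally consistent", {
  d <- make_surv(50, 6, beta = c(1, rep(0, 5)), seed = 23)
  path <- select_lambda_loocv(d$X, d$time, d$event, "ridge")
  expect_length(path$lambda, 100)
  expect_true(all(diff(path$lambda) < 0))
  expect_true(all(is.finite(path$cv_deviance)))
  expect_equal(path$lambda_min, path$lambda[which.min(path$cv_deviance)])
  expect_error(select_lambda_loocv(d$X[1:8, ], d$time[1:8], d$event[1:8]),
               "at least 10")
})

test_that("LOO-CV deviance matches cv.glmnet on the same folds and grid", {
  library(glmnet)
  d <- make_surv(45, 4, beta = c(0.7, 0, 0, 0), seed = 31)
  path <- select_lambda_loocv(d$X, d$time, d$event, "ridge")
  std <- standardize_columns(d$X)
  cv <- cv.glmnet(std$X, survival::Surv(d$time, d$event), family = "cox",
                  alpha = 0, lambda = path$lambda, foldid = seq_len(45),
                  grouped = TRUE, standardize = FALSE, thresh = 1e-11)
  expect_equal(path$lambda_min, cv$lambda.min, tolerance = 1e-10)
  expect_gt(cor(path$cv_deviance, cv$cvm), 0.99999)
})

test_that("lasso keeps the empty model on pure noise in most seeds", {
  empty <- 0L
  for (s in 1:20) {
    d <- make_surv(60, 10, beta = rep(0, 10), scale = 30, seed = 400 + s)
    path <- select_lambda_loocv(d$X, d$time, d$event, "lasso")
    b <- path$beta_std[, path$index_min]
    if (all(b == 0)) empty <- empty + 1L
  }
  expect_gte(empty, 14L)
})

test_that("a strong single signal dominates the selected lasso model", {
  hits <- 0L
  for (s in 1:20) {
    d <- make_surv(80, 6, beta = c(1.5, rep(0, 5)), scale = 30,
                   seed = 500 + s)
    path <- select_lambda_loocv(d$X, d$time, d$event, "lasso")
    b <- path$beta_std[, path$index_min]
    if (which.max(abs(b)) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("penalized logistic regression matches glm and glmnet", {
  set.seed(41)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(100, 1, plogis(0.3 + X[, 1]))
  fit0 <- logistic_penalized(X, y, "ridge", lambda = 0)
  ref <- glm(y ~ X, family = binomial())
  expect_lt(max(abs(c(fit0$intercept, fit0$beta) - coef(ref))), 1e-6)
  # lambda -> infinity: intercept-only model, fitted probability = prevalence
  fitI <- logistic_penalized(X, y, "ridge", lambda = 1e8)
  expect_lt(max(abs(fitI$beta)), 1e-6)
  expect_equal(unname(predict(fitI, X)[1]), mean(y), tolerance = 1e-4)
})

test_that("logistic sign recovery under a planted per-SD log-odds of one", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(600 + s)
    X <- matrix(rnorm(300 * 4), 300, 4,
                dimnames = list(NULL, paste0("g", 1:4)))
    y <- rbinom(300, 1, plogis(X[, 1]))
    fit <- logistic_penalized(X, y, "ridge")
    if (fit$beta_std[1] > 0) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("importance transform follows its closed form", {
  fit <- structure(list(beta_std = c(null = 0, dbl = log(2)),
                        baseline_cumhaz = data.frame(time = 10,
                                                     cumhaz = -log(0.6))),
                   class = "cox_fit")
  imp <- importance_s36(fit)
  expect_equal(imp$delta_s36[imp$variable == "null"], 0)
  expect_equal(imp$delta_s36[imp$variable == "dbl"], 0.6^2 - 0.6,
               tolerance = 1e-12)
  # sign(delta) is opposite to sign(beta_std) for baseline survival in (0,1)
  fit$beta_std <- c(pos = 0.8, neg = -0.8)
  imp2 <- importance_s36(fit)
  expect_lt(imp2$delta_s36[imp2$variable == "pos"], 0)
  expect_gt(imp2$delta_s36[imp2$variable == "neg"], 0)
  # no events before the horizon: all importances zero, with a warning
  fit$baseline_cumhaz <- data.frame(time = 50, cumhaz = 0.5)
  expect_warning(imp3 <- importance_s36(fit), "horizon")
  expect_equal(imp3$delta_s36, c(0, 0))
})

test_that("the seven model variable sets enumerate the design correctly", {
  sets <- model_variable_sets()
  expect_length(sets, 7)
  expect_length(sets[["Clinics"]], 6)
  expect_length(sets[["Sphingo"]], 38)
  expect_length(sets[["Immune"]], 8)
  expect_length(sets[["Clinics+Sphingo+Immune"]], 52)
  co <- generate_cohort(synthetic_config(n_samples = 10, seed = 1))
  D <- build_design(co, sets[["Clinics+Immune"]])
  expect_equal(dim(D), c(10, 14))
  Dd <- build_design(co, sets[["Clinics"]], figo_coding = "dummy")
  expect_true(all(c("figo_III", "figo_IV") %in% colnames(Dd)))
})
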