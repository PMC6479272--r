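#' Univariate Cox regression
#'
#' Hazard ratio with Wald 95% confidence interval and two-sided Wald p-value
#' from a single-covariate Cox model (Breslow tie handling).
#'
#' @param x numeric covariate.
#' @param time survival times (months), positive.
#' @param event event indicator (0/1); at least 2 events required.
#' @return List with `beta`, `se`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `converged`, `n`, `n_events`.
#' @export
cox_univariate <- function(x, time, event) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (sum(event) < 2) stop("at least 2 events required")
  if (sd(x) == 0) stop("covariate is constant")
  converged <- TRUE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, ties = "breslow"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  list(beta = beta, se = se, hr = exp(beta),
       ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
       p = 2 * pnorm(-abs(beta / se)),
       converged = converged, n = length(x), n_events = sum(event))
}

#' Standardize a covariate matrix (population SD)
#'
#' Centers each column at its mean and scales by the population standard
#' deviation (denominator n). Constant columns are an error.
#'
#' @param X numeric matrix.
#' @return List with `X` (standardized), `center`, `scale`.
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  sc <- sqrt(colMeans(X^2) - ctr^2)
  if (any(sc == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sc == 0], collapse = ", "))
  list(X = sweep(sweep(X, 2, ctr), 2, sc, "/"), center = ctr, scale = sc)
}

# score of the Breslow partial likelihood at beta = 0, divided by n;
# lambda_max for the lasso is max_j |score_j|
cox_null_score <- function(X, time, event) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]
  rs <- integer(n); start <- 1
  for (i in seq_len(n)) {
    if (t_s[i] > t_s[start]) start <- i
    rs[i] <- start
  }
  atrisk <- n - rs + 1
  cum <- cumsum_events_over_risk(d_s, rs, atrisk)
  g <- d_s - cum            # gradient at beta = 0 for sorted subjects
  g_un <- numeric(n); g_un[ord] <- g
  as.vector(crossprod(X, g_un)) / n
}

cumsum_events_over_risk <- function(d_s, rs, atrisk) {
  n <- length(d_s)
  contrib <- numeric(n)
  for (i in which(d_s == 1)) contrib[rs[i]] <- contrib[rs[i]] + 1 / atrisk[i]
  cumsum(contrib)
}

#' Penalty grid of lambda values
#'
#' 100 log-spaced values descending from `lambda_max` (the smallest lasso
#' penalty with an all-zero solution, from the null-model score) down to
#' `lambda_min_ratio * lambda_max`; the ridge grid is the same grid scaled up
#' 1000-fold, mirroring common elastic-net practice.
#'
#' @param X standardized covariate matrix.
#' @param time,event survival outcome (for the Cox score); for logistic grids
#'   pass `y` via `binary_y` instead.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param nlambda grid size.
#' @param lambda_min_ratio ratio of smallest to largest grid value.
#' @param ridge_scale multiplier applied to the ridge grid.
#' @param binary_y binary outcome for logistic grids.
#' @return Descending numeric vector of lambda values.
#' @export
lambda_grid <- function(X, time = NULL, event = NULL,
                        penalty = c("ridge", "lasso"), nlambda = 100,
                        lambda_min_ratio = 1e-4, ridge_scale = 1000,
                        binary_y = NULL) {
  penalty <- match.arg(penalty)
  if (!is.null(binary_y)) {
    score <- as.vector(crossprod(X, binary_y - mean(binary_y))) / nrow(X)
  } else {
    score <- cox_null_score(X, time, event)
  }
  lmax <- max(abs(score))
  if (lmax <= 0) lmax <- 1e-3
  grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                  length.out = nlambda))
  if (penalty == "ridge") grid <- grid * ridge_scale
  grid
}

penalty_alpha <- function(penalty) {
  switch(match.arg(penalty, c("ridge", "lasso")), ridge = 0, lasso = 1)
}

#' Penalized Cox regression
#'
#' Maximizes the Breslow-ties partial log-likelihood penalized by
#' `lambda * P(beta)` with `P` the ridge (`0.5 * sum(beta^2)`) or lasso
#' (`sum(|beta|)`) penalty on internally standardized covariates
#' (population SD), in the glmnet `-(1/n) loglik + lambda * P`
#' parametrization. Coefficients are reported on both the standardized scale
#' (`beta_std`, log hazard per SD) and the original per-unit scale. The
#' Breslow baseline cumulative hazard is evaluated with all covariates at
#' their sample means.
#'
#' @param X covariate matrix (samples x variables).
#' @param time,event survival outcome.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param lambda non-negative penalty weight (a single value).
#' @param maxit,tol IRLS iteration cap and convergence tolerance.
#' @return A `cox_fit`: `beta` (per unit), `beta_std` (per SD), `lambda`,
#'   `penalty`, `baseline_cumhaz` (data frame `time`, `cumhaz` at event
#'   times), `loglik`, `converged`, `n_iter`, `center`, `scale`, `excluded`
#'   (variables with zero lasso coefficient).
#' @export
cox_penalized <- function(X, time, event, penalty = c("ridge", "lasso"),
                          lambda, maxit = 200, tol = 1e-10) {
  penalty <- match.arg(penalty)
  if (lambda < 0) stop("lambda must be non-negative")
  X <- as.matrix(X)
  std <- standardize_columns(X)
  fit <- cpp_cox_path(std$X, time, event, penalty_alpha(penalty),
                      as.numeric(lambda), maxit = maxit, tol = tol)
  beta_std <- as.vector(fit$beta)
  if (penalty == "lasso") beta_std[abs(beta_std) < 1e-10] <- 0
  names(beta_std) <- colnames(X)
  eta <- as.vector(std$X %*% beta_std)
  structure(list(
    beta = beta_std / std$scale,
    beta_std = beta_std,
    lambda = lambda, penalty = penalty,
    baseline_cumhaz = breslow_cumhaz(time, event, eta),
    loglik = fit$loglik[1],
    converged = fit$iters[1] < fit$maxit,
    n_iter = fit$iters[1],
    center = std$center, scale = std$scale,
    excluded = names(beta_std)[penalty == "lasso" & beta_std == 0],
    eta = eta), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("penalized Cox fit (%s, lambda = %.4g): %d variables, %d nonzero\n",
              x$penalty, x$lambda, length(x$beta_std),
              sum(x$beta_std != 0)))
  invisible(x)
}

#' Breslow baseline cumulative hazard
#'
#' Step-function estimate at the distinct event times,
#' \eqn{H_0(t) = \sum_{t_j \le t} d_j / \sum_{l \in R(t_j)} e^{\eta_l}},
#' for the reference subject with linear predictor 0 (covariates at the
#' sample means when `eta` comes from a standardized fit).
#'
#' @param time,event survival outcome.
#' @param eta per-subject linear predictors.
#' @return Data frame with `time` (distinct event times) and `cumhaz`.
#' @export
breslow_cumhaz <- function(time, event, eta) {
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]; e_s <- exp(eta[ord])
  revcum <- rev(cumsum(rev(e_s)))
  rs <- integer(length(t_s)); start <- 1
  for (i in seq_along(t_s)) {
    if (t_s[i] > t_s[start]) start <- i
    rs[i] <- start
  }
  ev_times <- unique(t_s[d_s == 1])
  h <- vapply(ev_times, function(tt) {
    idx <- which(t_s == tt & d_s == 1)
    length(idx) / revcum[rs[idx[1]]]
  }, numeric(1))
  data.frame(time = ev_times, cumhaz = cumsum(h))
}

# step-function evaluation of a breslow table at arbitrary times
eval_cumhaz <- function(bh, t) {
  if (!nrow(bh)) return(rep(0, length(t)))
  idx <- findInterval(t, bh$time)
  c(0, bh$cumhaz)[idx + 1]
}

#' Leave-one-out cross-validated penalty selection
#'
#' Builds the [lambda_grid()] and evaluates, for every grid value, the
#' Verweij-van Houwelingen cross-validated partial-likelihood deviance
#' \eqn{-2 \sum_i [l(\hat\beta_{(-i)}) - l_{(-i)}(\hat\beta_{(-i)})]} over
#' leave-one-out folds. The chosen lambda minimizes the deviance on the
#' grid.
#'
#' @param X covariate matrix (standardized internally).
#' @param time,event survival outcome; needs `n >= 10` and at least 5
#'   events.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param nlambda,lambda_min_ratio,ridge_scale grid parameters.
#' @param maxit,tol inner IRLS controls.
#' @return A `lambda_path`: `lambda` (descending grid), `cv_deviance`,
#'   `lambda_min`, `index_min`, `n_folds_used`, plus the full-data
#'   standardized coefficient path `beta_std` (variables x lambdas) with the
#'   standardization `center` and `scale`.
#' @export
select_lambda_loocv <- function(X, time, event, penalty = c("ridge", "lasso"),
                                nlambda = 100, lambda_min_ratio = 1e-4,
                                ridge_scale = 1000, maxit = 50, tol = 1e-6) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("at least 10 subjects required")
  if (sum(event) < 5) stop("at least 5 events required")
  std <- standardize_columns(X)
  grid <- lambda_grid(std$X, time, event, penalty, nlambda,
                      lambda_min_ratio, ridge_scale)
  cv <- cpp_cox_cvl(std$X, time, event, penalty_alpha(penalty), grid,
                    seq_len(n), maxit = maxit, tol = tol)
  ok <- as.logical(cv$fold_ok)
  if (!all(ok))
    warning(sum(!ok), " event-free fold(s) skipped")
  dev <- -2 * colSums(cv$cvl[ok, , drop = FALSE])
  if (any(!is.finite(dev))) stop("non-finite CV deviance encountered")
  imin <- which.min(dev)
  beta_std <- cv$beta_full
  if (penalty == "lasso") beta_std[abs(beta_std) < 1e-10] <- 0
  rownames(beta_std) <- colnames(X)
  structure(list(lambda = grid, cv_deviance = dev,
                 lambda_min = grid[imin], index_min = imin,
                 n_folds_used = sum(ok), penalty = penalty,
                 beta_std = beta_std, center = std$center,
                 scale = std$scale),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf("%s LOO-CV path: %d lambdas, min deviance %.3f at lambda = %.4g\n",
              x$penalty, length(x$lambda), min(x$cv_deviance), x$lambda_min))
  invisible(x)
}

#' Penalized logistic regression with LOO-CV penalty selection
#'
#' Penalized Bernoulli likelihood (unpenalized intercept) on internally
#' standardized covariates. When `lambda` is `NULL` it is selected by
#' minimizing the leave-one-out cross-validated binomial deviance over the
#' [lambda_grid()].
#'
#' @param X covariate matrix.
#' @param y binary response (both classes present).
#' @param penalty `"ridge"` or `"lasso"`.
#' @param lambda penalty weight, or `NULL` for LOO-CV selection.
#' @param nlambda,lambda_min_ratio,ridge_scale grid parameters.
#' @param maxit,tol IRLS controls.
#' @return A `logit_fit`: `intercept`, `beta` (per unit), `beta_std`
#'   (per SD), `lambda`, `cv` (the deviance path when CV-selected),
#'   `center`, `scale`, `converged`.
#' @export
logistic_penalized <- function(X, y, penalty = c("ridge", "lasso"),
                               lambda = NULL, nlambda = 100,
                               lambda_min_ratio = 1e-4, ridge_scale = 1000,
                               maxit = 100, tol = 1e-9) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both response classes must be present")
  std <- standardize_columns(X)
  alpha <- penalty_alpha(penalty)
  cv <- NULL
  if (is.null(lambda)) {
    grid <- lambda_grid(std$X, penalty = penalty, nlambda = nlambda,
                        lambda_min_ratio = lambda_min_ratio,
                        ridge_scale = ridge_scale, binary_y = y)
    cvres <- cpp_logit_cvdev(std$X, y, alpha, grid, seq_len(nrow(X)),
                             maxit = 50, tol = 1e-6)
    ok <- as.logical(cvres$fold_ok)
    dev <- colSums(cvres$dev[ok, , drop = FALSE])
    lambda <- grid[which.min(dev)]
    cv <- list(lambda = grid, cv_deviance = dev, lambda_min = lambda,
               n_folds_used = sum(ok))
  }
  fit <- cpp_logit_path(std$X, y, alpha, as.numeric(lambda),
                        maxit = maxit, tol = tol)
  coefs <- as.vector(fit$coefs)
  beta_std <- coefs[-1]
  names(beta_std) <- colnames(X)
  # map intercept back to the original covariate scale
  beta <- beta_std / std$scale
  intercept <- coefs[1] - sum(beta * std$center)
  structure(list(intercept = intercept, beta = beta, beta_std = beta_std,
                 lambda = lambda, penalty = penalty, cv = cv,
                 center = std$center, scale = std$scale,
                 converged = fit$iters[1] < fit$maxit),
            class = "logit_fit")
}

#' Predict response probabilities from a penalized logistic fit
#' @param object a `logit_fit`.
#' @param newdata covariate matrix on the original scale.
#' @param ... unused.
#' @return Vector of probabilities.
#' @export
predict.logit_fit <- function(object, newdata, ...) {
  eta <- object$intercept +
    as.vector(as.matrix(newdata)[, names(object$beta), drop = FALSE] %*%
                object$beta)
  plogis(eta)
}

#' Variable importance as the 36-month survival-probability shift
#'
#' Transforms standardized coefficients into the clinically readable scale:
#' with `S36` the estimated 36-month survival of the reference subject (all
#' covariates at their sample means, Breslow baseline), a variable's
#' importance is
#' \eqn{\Delta S^{36}_j = (S^{36})^{\exp(\beta^*_j)} - S^{36},}
#' the change in 36-month survival for a subject one standard deviation
#' above the mean on that variable. Ranking by `|beta_std|` and by
#' `|delta_s36|` coincide for a fixed baseline.
#'
#' @param fit a [cox_penalized()] fit.
#' @param horizon months (default 36).
#' @return Data frame (`variable`, `beta_std`, `s36`, `delta_s36`), sorted
#'   by decreasing `|beta_std|`, with the baseline survival as attribute
#'   `s_baseline`.
#' @export
importance_s36 <- function(fit, horizon = 36) {
  stopifnot(inherits(fit, "cox_fit"))
  bh <- fit$baseline_cumhaz
  H <- eval_cumhaz(bh, horizon)
  if (!nrow(bh) || bh$time[1] > horizon) {
    warning("no events at or before the horizon; all importances are 0")
    H <- 0
  }
  s36 <- exp(-H)
  d <- s36^exp(fit$beta_std) - s36
  out <- data.frame(variable = names(fit$beta_std),
                    beta_std = unname(fit$beta_std),
                    s36 = s36, delta_s36 = unname(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$beta_std)), ]
  rownames(out) <- NULL
  attr(out, "s_baseline") <- s36
  out
}

#' The seven prognostic model variable sets
#'
#' Enumerates the model specifications compared in the analysis: the six
#' clinicopathological covariates (`Clinics`), the 38 sphingolipid /
#' lysophosphatidate genes (`Sphingo`), the 8 immune markers (`Immune`), and
#' all their combinations.
#'
#' @param signature a [gene_signature].
#' @return Named list of character vectors of design-column names.
#' @export
model_variable_sets <- function(signature = default_signature()) {
  sph <- signature$genes$symbol[signature$genes$category == "sphingo_lpa"]
  imm <- signature$genes$symbol[signature$genes$category == "immune"]
  clin <- c("age", "histology", "figo", "grade", "peritoneal", "residual")
  list(
    "Clinics" = clin,
    "Sphingo" = sph,
    "Immune" = imm,
    "Sphingo+Immune" = c(sph, imm),
    "Clinics+Sphingo" = c(clin, sph),
    "Clinics+Immune" = c(clin, imm),
    "Clinics+Sphingo+Immune" = c(clin, sph, imm))
}

#' Design matrix for a model specification
#'
#' Binds expression variables and clinicopathological covariates into one
#' numeric design matrix. FIGO stage and residual disease are coded as
#' single ordinal covariates by default (II/III/IV -> 0/1/2; none/<=1cm/>1cm
#' -> 0/1/2), preserving the six-covariate clinical model; dummy coding is
#' available.
#'
#' @param cohort a `cohort` (or any list with `expression` and `clinical`).
#' @param variables character vector of design-column names (see
#'   [model_variable_sets()]).
#' @param figo_coding `"ordinal"` or `"dummy"`.
#' @return Numeric matrix, samples x variables.
#' @export
build_design <- function(cohort, variables, figo_coding = c("ordinal", "dummy")) {
  figo_coding <- match.arg(figo_coding)
  expr <- as_plain_matrix(cohort$expression)
  cl <- cohort$clinical
  clin <- cbind(age = cl$age, histology = cl$histology, figo = cl$figo,
                grade = cl$grade, peritoneal = cl$peritoneal,
                residual = cl$residual)
  if (figo_coding == "dummy") {
    clin <- cbind(clin[, setdiff(colnames(clin), "figo")],
                  figo_III = as.integer(cl$figo == 1),
                  figo_IV = as.integer(cl$figo == 2))
    variables <- unlist(lapply(variables, function(v)
      if (v == "figo") c("figo_III", "figo_IV") else v))
  }
  rownames(clin) <- cl$sample_id
  D <- cbind(expr, clin[rownames(expr), , drop = FALSE])
  missing <- setdiff(variables, colnames(D))
  if (length(missing))
    stop("variables absent from the cohort: ", paste(missing, collapse = ", "))
  D[, variables, drop = FALSE]
}
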