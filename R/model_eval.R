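#' Outer leave-one-out cross-validated linear predictors
#'
#' Wraps an outer leave-one-out loop around the entire model development
#' process: for each held-out subject the remaining data are standardized,
#' the penalty weight is selected by inner leave-one-out cross-validation
#' ([select_lambda_loocv()]), the penalized Cox model is fitted, and the
#' held-out subject's linear predictor is computed with the training-fold
#' standardization. No quantity entering subject i's prediction ever saw
#' subject i. The procedure is deterministic given the data.
#'
#' @param X covariate matrix (samples x variables, original scale).
#' @param time,event survival outcome; needs `n >= 20` and at least 10
#'   events.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param nlambda,lambda_min_ratio,ridge_scale grid parameters passed to
#'   the inner selection.
#' @return A `cv_predictions`: `eta` (named per-sample cross-validated
#'   linear predictor, log-hazard scale), `lambda` (chosen per fold),
#'   `n_failed` (folds where development failed; those predictions fall
#'   back to the training mean, i.e. 0).
#' @export
loocv_predictors <- function(X, time, event, penalty = c("ridge", "lasso"),
                             nlambda = 100, lambda_min_ratio = 1e-4,
                             ridge_scale = 1000) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 20) stop("at least 20 subjects required")
  if (sum(event) < 10) stop("at least 10 events required")
  eta <- numeric(n)
  lambda <- numeric(n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      path <- select_lambda_loocv(X[-i, , drop = FALSE], time[-i], event[-i],
                                  penalty = penalty, nlambda = nlambda,
                                  lambda_min_ratio = lambda_min_ratio,
                                  ridge_scale = ridge_scale)
      bstd <- path$beta_std[, path$index_min]
      list(eta = sum((X[i, ] - path$center) / path$scale * bstd),
           lambda = path$lambda_min)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      eta[i] <- 0 # training-mean linear predictor
      lambda[i] <- NA_real_
    } else {
      eta[i] <- res$eta
      lambda[i] <- res$lambda
    }
  }
  if (n_failed > 0)
    warning(n_failed, " outer fold(s) failed; predictions set to training mean")
  names(eta) <- rownames(X)
  structure(list(eta = eta, lambda = lambda, n_failed = n_failed,
                 penalty = penalty), class = "cv_predictions")
}

#' Harrell's concordance index
#'
#' Fraction of usable subject pairs in which the higher predicted risk has
#' the shorter survival. A pair is usable when the two observed times differ
#' and the shorter time is an event; tied predictions count 1/2.
#'
#' @param eta per-subject risk predictions (higher = worse).
#' @param time,event survival outcome.
#' @return The concordance fraction in `[0, 1]`.
#' @export
c_index <- function(eta, time, event) {
  n <- length(eta)
  stopifnot(length(time) == n, length(event) == n)
  ti <- matrix(time, n, n)
  usable <- (ti < t(ti)) & matrix(event == 1, n, n)
  if (!any(usable)) stop("no usable pairs")
  ei <- matrix(eta, n, n)
  conc <- ei > t(ei)   # shorter-time subject (row) has higher risk
  tied <- ei == t(ei)
  (sum(conc[usable]) + 0.5 * sum(tied[usable])) / sum(usable)
}

# Kaplan-Meier as a right-continuous step function S(t); returns a function.
km_stepfun <- function(time, event) {
  sf <- survfit(Surv(time, event) ~ 1)
  stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
}

# left-continuous evaluation S(t-)
km_left <- function(sfun, t) {
  vapply(t, function(tt) sfun(tt - 1e-9 * max(tt, 1)), numeric(1))
}

#' Schemper-Henderson proportion of explained variation
#'
#' The relative reduction in time-averaged absolute prediction error of the
#' covariate model versus the marginal Kaplan-Meier:
#' \eqn{V = (D - D_x) / D}. At each distinct event time t the per-subject
#' absolute error is \eqn{1 - S(t|x)} if the subject is known alive at t,
#' \eqn{S(t|x)} if dead by t, and for a subject censored at \eqn{c \le t}
#' the conditional mixture
#' \eqn{[S(t|x)/S(c|x)](1 - S(t|x)) + [1 - S(t|x)/S(c|x)] S(t|x)}.
#' `D` evaluates these with the marginal Kaplan-Meier, `D_x` with a Cox
#' model on `eta` as single covariate; event times are weighted by the
#' number of events divided by the Kaplan-Meier estimate of the censoring
#' distribution just before t (inverse-probability-of-censoring weights).
#'
#' @param eta per-subject predictions (any risk scale); a constant vector
#'   yields exactly 0.
#' @param time,event survival outcome with at least 5 events.
#' @return The explained-variation fraction `V`. In small cohorts the
#'   estimate can fall slightly below 0 when the censoring-distribution
#'   Kaplan-Meier is near 0 at a late event time and its
#'   inverse-probability weight dominates.
#' @export
pev <- function(eta, time, event) {
  n <- length(eta)
  if (sum(event) < 5) stop("at least 5 events required")
  ev_times <- sort(unique(time[event == 1]))
  d_t <- vapply(ev_times, function(tt) sum(time == tt & event == 1),
                numeric(1))
  # censoring-distribution KM, evaluated just before each event time
  G <- km_stepfun(time, 1 - event)
  wt <- d_t / pmax(km_left(G, ev_times), .Machine$double.eps)
  wt <- wt / sum(wt)

  S_marg <- km_stepfun(time, event)
  marg_t <- vapply(ev_times, S_marg, numeric(1))      # S(t) per event time
  marg_c <- vapply(time, S_marg, numeric(1))          # S(T_i) per subject

  mean_abs_error <- function(surv_t, surv_ci) {
    # surv_t: n x T matrix of S(t | x_i); surv_ci: length-n vector S(T_i | x_i)
    D <- numeric(length(ev_times))
    for (k in seq_along(ev_times)) {
      tt <- ev_times[k]
      st <- surv_t[, k]
      err <- ifelse(time > tt, 1 - st,
             ifelse(event == 1, st, {
               w <- ifelse(surv_ci > 0, pmin(st / surv_ci, 1), 0)
               w * (1 - st) + (1 - w) * st
             }))
      D[k] <- mean(err)
    }
    sum(wt * D)
  }

  marg_mat <- matrix(marg_t, n, length(ev_times), byrow = TRUE)
  D <- mean_abs_error(marg_mat, marg_c)

  if (sd(eta) == 0) {
    warning("constant predictor; explained variation is 0")
    return(0)
  }
  cfit <- coxph(Surv(time, event) ~ eta, ties = "breslow")
  bh <- basehaz(cfit, centered = FALSE)
  H <- stats::stepfun(bh$time, c(0, bh$hazard), right = FALSE)
  risk <- exp(unname(coef(cfit)) * eta)
  H_t <- vapply(ev_times, H, numeric(1))
  surv_t <- exp(-outer(risk, H_t))                    # n x T
  surv_ci <- exp(-risk * vapply(time, H, numeric(1)))
  D_x <- mean_abs_error(surv_t, surv_ci)

  (D - D_x) / D
}

#' Global p-value of a cross-validated predictor
#'
#' Two-sided Wald p-value from a univariate Cox model with the
#' cross-validated predictor as single covariate.
#'
#' @param eta cross-validated linear predictors.
#' @param time,event survival outcome.
#' @return p-value; a constant predictor returns 1 with a warning.
#' @export
global_p <- function(eta, time, event) {
  if (sd(eta) == 0) {
    warning("constant predictor; p = 1")
    return(1)
  }
  cox_univariate(eta, time, event)$p
}

#' Added-value test of a gene-derived predictor over the clinical predictor
#'
#' Likelihood-ratio test of the gene-derived cross-validated predictor's
#' coefficient in a bivariable Cox model containing both cross-validated
#' predictors. Near-collinear predictors (|r| > 0.999) fall back to the Wald
#' test with a warning.
#'
#' @param eta_clinical,eta_omics cross-validated linear predictors from
#'   outer LOO on the same cohort.
#' @param time,event survival outcome.
#' @return Two-sided p-value for added value.
#' @export
added_value_test <- function(eta_clinical, eta_omics, time, event) {
  if (sd(eta_omics) == 0) return(1)
  r <- if (sd(eta_clinical) == 0) 0 else cor(eta_clinical, eta_omics)
  if (abs(r) > 0.999) {
    warning("near-collinear predictors; Wald fallback")
    fit <- coxph(Surv(time, event) ~ eta_clinical + eta_omics,
                 ties = "breslow")
    se <- sqrt(diag(fit$var))[2]
    b <- coef(fit)[2]
    if (!is.finite(b) || !is.finite(se) || se == 0) return(1)
    return(unname(2 * pnorm(-abs(b / se))))
  }
  full <- coxph(Surv(time, event) ~ eta_clinical + eta_omics,
                ties = "breslow")
  reduced <- coxph(Surv(time, event) ~ eta_clinical, ties = "breslow")
  lr <- 2 * (full$loglik[2] - reduced$loglik[2])
  pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}

#' Quartile risk groups with Kaplan-Meier curves and log-rank test
#'
#' Stratifies the cohort by the 25th and 75th percentiles
#' (linear-interpolation quantiles) of the cross-validated predictor:
#' predictors strictly below Q1 form the low-risk group, strictly above Q3
#' the high-risk group, the rest the intermediate group. Kaplan-Meier curves
#' are estimated per group and compared with the k-group log-rank test.
#'
#' @param eta cross-validated linear predictors; `n >= 8`.
#' @param time,event survival outcome.
#' @return A `risk_stratification`: `thresholds` (Q1, Q3), `group` (factor
#'   per sample), `km` (per-group data frames `time`, `surv`, `n_risk`),
#'   `logrank` (`chisq`, `df`, `p`).
#' @export
risk_groups_km <- function(eta, time, event) {
  n <- length(eta)
  if (n < 8) stop("at least 8 subjects required")
  q <- quantile(eta, c(0.25, 0.75), type = 7, names = FALSE)
  group <- factor(ifelse(eta < q[1], "low",
                  ifelse(eta > q[2], "high", "intermediate")),
                  levels = c("low", "intermediate", "high"))
  used <- droplevels(group)
  if (nlevels(used) < nlevels(group))
    warning("empty risk group(s); log-rank df adjusted")
  km <- lapply(split(seq_len(n), group), function(idx) {
    if (!length(idx)) return(data.frame(time = numeric(0), surv = numeric(0),
                                        n_risk = integer(0)))
    sf <- survfit(Surv(time[idx], event[idx]) ~ 1)
    data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk)
  })
  lr <- survdiff(Surv(time, event) ~ used)
  df <- nlevels(used) - 1
  structure(list(thresholds = c(q1 = q[1], q3 = q[2]), group = group,
                 km = km,
                 logrank = list(chisq = unname(lr$chisq), df = df,
                                p = pchisq(unname(lr$chisq), df,
                                           lower.tail = FALSE))),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("risk groups (Q1 = %.3f, Q3 = %.3f): %s; log-rank chisq = %.3f (df %d), p = %.3g\n",
              x$thresholds[1], x$thresholds[2],
              paste(sprintf("%s %d", levels(x$group), table(x$group)),
                    collapse = ", "),
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

# rank-based (Mann-Whitney) AUC
auc_rank <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified k-fold validation of response models
#'
#' Validates penalized logistic models of a binary endpoint by repeated
#' stratified k-fold cross-validation: in each repeat the cohort is split
#' into k folds preserving class balance, each fold is predicted by a model
#' developed (including inner LOO penalty selection) on the other folds, and
#' the repeat's cross-validated AUC and binomial deviance are recorded.
#' When a reference design (e.g. clinics only) is supplied, it is validated
#' on the same folds, and an added-value likelihood-ratio test of the new
#' model's cross-validated linear predictor over the reference predictor is
#' performed per repeat.
#'
#' @param X covariate matrix.
#' @param y binary response; each class must have at least `k` members.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param seed integer; fold assignments derive deterministically from it.
#' @param X_reference optional reference design for the added-value
#'   comparison.
#' @return A `response_validation`: `auc` (per repeat), `deviance`,
#'   `summary` (mean and SD), and when a reference is given `auc_reference`
#'   and `added_value_p` (per-repeat p-values and their median).
#' @export
repeated_kfold_response <- function(X, y, penalty = c("ridge", "lasso"),
                                    k = 5, repeats = 40, seed = 1,
                                    X_reference = NULL) {
  penalty <- match.arg(penalty)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (min(table(y)) < k)
    stop("each response class needs at least k members for stratification")
  n <- length(y)
  folds <- with_seed(seed, lapply(seq_len(repeats), function(r) {
    fid <- integer(n)
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fid[idx] <- rep_len(seq_len(k), length(idx))
    }
    fid
  }))
  cv_linpred <- function(design, fid) {
    lp <- numeric(n)
    for (f in seq_len(k)) {
      test <- which(fid == f)
      fit <- logistic_penalized(design[-test, , drop = FALSE], y[-test],
                                penalty = penalty)
      lp[test] <- fit$intercept +
        as.vector(design[test, , drop = FALSE] %*% fit$beta)
    }
    lp
  }
  auc <- dev <- auc_ref <- av_p <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fid <- folds[[r]]
    lp <- cv_linpred(X, fid)
    pr <- plogis(lp)
    auc[r] <- auc_rank(pr, y)
    prc <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    dev[r] <- -2 * sum(y * log(prc) + (1 - y) * log(1 - prc))
    if (!is.null(X_reference)) {
      lpr <- cv_linpred(as.matrix(X_reference), fid)
      auc_ref[r] <- auc_rank(plogis(lpr), y)
      full <- stats::glm(y ~ lpr + lp, family = stats::binomial())
      red <- stats::glm(y ~ lpr, family = stats::binomial())
      av_p[r] <- pchisq(max(red$deviance - full$deviance, 0), df = 1,
                        lower.tail = FALSE)
    }
  }
  out <- list(auc = auc, deviance = dev,
              summary = c(auc_mean = mean(auc), auc_sd = sd(auc),
                          deviance_mean = mean(dev), deviance_sd = sd(dev)),
              k = k, repeats = repeats, seed = seed, penalty = penalty)
  if (!is.null(X_reference)) {
    out$auc_reference <- auc_ref
    out$added_value_p <- av_p
    out$summary <- c(out$summary,
                     auc_reference_mean = mean(auc_ref),
                     added_value_p_median = median(av_p))
  }
  structure(out, class = "response_validation")
}

#' Performance report for one model specification
#'
#' Bundles the validation metrics computed from cross-validated predictors:
#' proportion of explained variation, concordance index, global p, and
#' (when a clinical reference predictor is supplied) the added-value p.
#'
#' @param eta cross-validated predictors of the model.
#' @param time,event survival outcome.
#' @param eta_clinical optional clinical-model cross-validated predictors.
#' @return A `performance_report` list: `pev`, `c_index`, `global_p`,
#'   `added_value_p` (or `NA`), `n`, `n_events`.
#' @export
performance_report <- function(eta, time, event, eta_clinical = NULL) {
  structure(list(
    pev = pev(eta, time, event),
    c_index = c_index(eta, time, event),
    global_p = global_p(eta, time, event),
    added_value_p = if (is.null(eta_clinical)) NA_real_
                    else added_value_test(eta_clinical, eta, time, event),
    n = length(eta), n_events = sum(event)), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("PEV %.2f%%  c-index %.3f  global p %.3g%s  (n = %d, events = %d)\n",
              100 * x$pev, x$c_index, x$global_p,
              if (is.na(x$added_value_p)) ""
              else sprintf("  added-value p %.3g", x$added_value_p),
              x$n, x$n_events))
  invisible(x)
}
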