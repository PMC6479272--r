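# Straight-line reference implementations used as independent oracles.
# These deliberately share no code with the package: plain loops, textbook
# formulas.

# Harrell concordance by explicit pair enumeration: usable pairs have
# distinct times with the shorter time an event; prediction ties score 1/2.
oracle_cindex <- function(eta, time, event) {
  num <- den <- 0
  n <- length(eta)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      shorter <- if (time[i] < time[j]) i else j
      longer <- if (time[i] < time[j]) j else i
      if (event[shorter] != 1) next
      den <- den + 1
      if (eta[shorter] > eta[longer]) num <- num + 1
      else if (eta[shorter] == eta[longer]) num <- num + 0.5
    }
  }
  num / den
}

# product-limit estimator as an explicit table (no survival package)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    d <- sum(time == ut[k] & event == 1)
    r <- sum(time >= ut[k])
    s <- s * (1 - d / r)
    surv[k] <- s
  }
  list(time = ut, surv = surv)
}

oracle_km_eval <- function(km, t) {
  s <- 1
  for (k in seq_along(km$time)) if (km$time[k] <= t) s <- km$surv[k]
  s
}

# Schemper-Henderson explained variation, written out longhand with its own
# Kaplan-Meier; the model survival curves are taken from a coxph fit on eta.
oracle_pev <- function(eta, time, event) {
  n <- length(eta)
  km <- oracle_km(time, event)
  kmc <- oracle_km(time, 1 - event) # censoring distribution
  ev_times <- sort(unique(time[event == 1]))
  fit <- survival::coxph(survival::Surv(time, event) ~ eta, ties = "breslow")
  bh <- survival::basehaz(fit, centered = FALSE)
  H_at <- function(t) {
    h <- 0
    for (k in seq_len(nrow(bh))) if (bh$time[k] <= t) h <- bh$hazard[k]
    h
  }
  beta <- unname(coef(fit))
  S_model <- function(t, i) exp(-H_at(t) * exp(beta * eta[i]))
  S_marg <- function(t) oracle_km_eval(km, t)
  G_left <- function(t) {
    s <- 1
    for (k in seq_along(kmc$time)) if (kmc$time[k] < t) s <- kmc$surv[k]
    s
  }
  err_one <- function(st, sci, ti, di, t) {
    if (ti > t) return(1 - st)
    if (di == 1) return(st)
    w <- if (sci > 0) min(st / sci, 1) else 0
    w * (1 - st) + (1 - w) * st
  }
  wsum <- Dm <- Dx <- 0
  for (t in ev_times) {
    d <- sum(time == t & event == 1)
    w <- d / G_left(t)
    em <- ex <- 0
    for (i in seq_len(n)) {
      em <- em + err_one(S_marg(t), S_marg(time[i]), time[i], event[i], t)
      ex <- ex + err_one(S_model(t, i), S_model(time[i], i), time[i],
                         event[i], t)
    }
    Dm <- Dm + w * em / n
    Dx <- Dx + w * ex / n
    wsum <- wsum + w
  }
  (Dm - Dx) / Dm
}

# UPGMA by brute force: cluster distances recomputed from the original
# dissimilarity matrix at every step (no Lance-Williams update); same
# lexicographic smallest-leaf tie rule as the package.
oracle_upgma <- function(d0) {
  n <- nrow(d0)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    best_d <- Inf
    best_lex <- c(Inf, Inf)
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        dd <- mean(d0[clusters[[a]], clusters[[b]]])
        lex <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        better <- dd < best_d - 1e-12 ||
          (abs(dd - best_d) <= 1e-12 &&
           (lex[1] < best_lex[1] ||
            (lex[1] == best_lex[1] && lex[2] < best_lex[2])))
        if (better) {
          best_d <- dd
          best <- c(a, b)
          best_lex <- lex
        }
      }
    }
    a <- best[1]; b <- best[2]
    merges[step, ] <- sort(c(ids[a], ids[b]))
    heights[step] <- best_d
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    ids[a] <- step
    clusters[[b]] <- NULL
    ids <- ids[-b]
  }
  list(merge = merges, height = heights)
}

# Breslow partial log-likelihood, plain loops (for the optimizer oracle)
oracle_cox_loglik <- function(beta, X, time, event) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# small right-censored survival data set
make_surv <- function(n, p, beta = rep(0, p), shape = 1.3, scale = 40,
                      cens = c(12, 49), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  lp <- as.vector(X %*% beta)
  t_ev <- scale * (-log(runif(n)) * exp(-lp))^(1 / shape)
  cc <- runif(n, cens[1], cens[2])
  list(X = X, time = pmin(t_ev, cc), event = as.integer(t_ev <= cc))
}
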