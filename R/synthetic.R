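#' Default correlation-block layout of the synthetic cohort
#'
#' Gene blocks mirror the co-expression structure seen in signature-profiled
#' ovarian tumours: an immune-core block (the 8 immune lineage markers plus
#' S1PR4 and CD1B) that separates immune-low from immune-high tumours, a
#' myeloid-associated sphingolipid block co-varying with the immune
#' infiltrate, three sphingolipid enzyme/receptor blocks expressed inversely
#' to the immune context, and a residual weakly correlated block. Shifts are
#' per-subtype mean displacements on the log2 scale in the order (immune_low,
#' mixed, immune_high).
#'
#' @param immune_shift half-separation (log2 units) between the immune-low
#'   and immune-high subtype means on the immune-core block; the planted
#'   low/high contrast is `2 * immune_shift`.
#' @return List of block definitions (`name`, `genes`, `rho`, `shift`).
#' @export
default_gene_blocks <- function(immune_shift = 2) {
  s <- immune_shift
  list(
    list(name = "immune_core",
         genes = c("MS4A1", "IGHG1", "IGHM", "CD14", "CD68", "CD163", "CD3E",
                   "PTPRC", "S1PR4", "CD1B"),
         rho = 0.6, shift = c(-s, 0, s)),
    list(name = "myeloid_sphingo",
         genes = c("SPHK1", "LPAR4", "S1PR5", "LPAR1", "PPAP2A", "S1PR1",
                   "SMPD1", "CD1D", "ENPP2", "LPAR6", "NAAA", "LPAR5"),
         rho = 0.4, shift = c(-0.5, 0, 0.5)),
    list(name = "sphingo_sm_salvage",
         genes = c("PPAP2C", "SGPP2", "SMPD3", "SGMS1", "SMPD2", "CERS3"),
         rho = 0.5, shift = c(0.4, 0, -0.4)),
    list(name = "sphingo_receptor",
         genes = c("CERS4", "S1PR2", "CERS6", "CERS5", "LPAR2", "SGPL1",
                   "CERS2"),
         rho = 0.5, shift = c(0.4, 0, -0.4)),
    list(name = "sphingo_kinase",
         genes = c("PPAP2B", "S1PR3", "SPHK2", "CERK"),
         rho = 0.5, shift = c(0.4, 0, -0.4)),
    list(name = "residual",
         genes = c("SGPP1", "SGMS2", "UGT8", "UGCG", "CERS1", "LPAR3",
                   "ASAH1"),
         rho = 0.2, shift = c(0, 0, 0)))
}

# Clinicopathological marginals of an advanced-stage EOC cohort: age at
# diagnosis, serous histology, FIGO stage II/III/IV, grade 3, peritoneal
# carcinomatosis, residual disease after surgery (none / <=1cm / >1cm).
default_clinical_marginals <- function() {
  list(age_mean = 56, age_sd = 10.5, age_range = c(25, 85),
       p_serous = 0.884,
       p_figo = c(II = 0.046, III = 0.804, IV = 0.150),
       p_grade3 = 0.723,
       p_peritoneal = 0.699,
       p_residual = c(none = 0.734, le1cm = 0.173, gt1cm = 0.093))
}

# Per-unit log-hazard contributions on the generated scale.  Gene effects
# carry the protective direction seen for CD68 / LPAR3 / SMPD2 / CD1B
# (higher expression, lower hazard); clinical effects reflect stage, grade,
# carcinomatosis and residual disease as adverse factors.
default_beta_survival <- function() {
  c(CD68 = -0.19, LPAR3 = -0.12, SMPD2 = -0.48, CD1B = -0.07,
    age = 0.025, figo = 0.35, grade = 0.25, peritoneal = 0.30,
    residual = 0.35, histology = 0.10)
}

# Log-odds of response to platinum-based chemotherapy; immune-rich tumours
# respond more often.
default_beta_response <- function() {
  c(CD3E = 0.30, CD68 = 0.20, PTPRC = 0.20)
}

#' Configuration of the synthetic-cohort generator
#'
#' Defines every aspect of a simulated signature-profiling study: cohort
#' size, planted immune-low/mixed/high subtype proportions, block-correlated
#' log2 expression with subtype mean shifts, clinical covariate marginals,
#' Weibull survival driven by a proportional-hazards linear predictor with
#' uniform administrative censoring, a logistic treatment-response model, and
#' an MCAR missingness rate.
#'
#' Default values emulate a 173-patient advanced epithelial ovarian cancer
#' cohort: subtype split 47/70/56 (low/mixed/high), ~29% deaths and ~57%
#' recurrences over a follow-up window of 12-49 months, ~73% responders.
#'
#' @param n_samples number of patients.
#' @param subtype_proportions length-3 non-negative vector (low, mixed, high)
#'   summing to 1.
#' @param gene_blocks list of blocks, each `list(name, genes, rho, shift)`
#'   with exchangeable within-block correlation `rho` and per-subtype mean
#'   shifts `shift` (low, mixed, high) in log2 units.
#' @param noise_sd independent gaussian noise added on top of the block
#'   structure (log2 units).
#' @param beta_true_survival named per-unit log-hazard coefficients over
#'   generated genes and clinical covariates.
#' @param weibull_shape,weibull_scale Weibull baseline for overall survival
#'   (scale in months).
#' @param weibull_scale_pfs Weibull scale for progression-free survival.
#' @param censoring_window `c(c_min, c_max)` months of uniform administrative
#'   censoring.
#' @param beta_true_response named log-odds coefficients of the response
#'   model.
#' @param response_intercept log-odds intercept of the response model.
#' @param missing_rate MCAR missingness rate applied to the expression
#'   matrix, in `[0, 1)`.
#' @param clinical_marginals marginal distributions of the clinical
#'   covariates (see `default_clinical_marginals`).
#' @param seed integer; generation is a pure function of the configuration
#'   including this seed.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_samples = 173,
                             subtype_proportions = c(low = 47, mixed = 70,
                                                     high = 56) / 173,
                             gene_blocks = default_gene_blocks(),
                             noise_sd = 0.3,
                             beta_true_survival = default_beta_survival(),
                             weibull_shape = 1.3,
                             weibull_scale = 76,
                             weibull_scale_pfs = 46,
                             censoring_window = c(12, 49),
                             beta_true_response = default_beta_response(),
                             response_intercept = 1.2,
                             missing_rate = 0,
                             clinical_marginals = default_clinical_marginals(),
                             seed = 1) {
  if (length(subtype_proportions) != 3 || any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must be 3 non-negative values summing to 1")
  if (!length(gene_blocks)) stop("gene_blocks must not be empty")
  genes <- unlist(lapply(gene_blocks, `[[`, "genes"))
  if (anyDuplicated(genes))
    stop("a gene may belong to only one block")
  for (b in gene_blocks) {
    m <- length(b$genes)
    if (m < 1) stop("empty gene block: ", b$name)
    if (b$rho >= 1 || (m > 1 && b$rho < -1 / (m - 1)))
      stop(sprintf(
        "block '%s': rho = %g gives a non-positive-semidefinite covariance (need -1/(m-1) <= rho < 1)",
        b$name, b$rho))
    if (length(b$shift) != 3) stop("block shifts must be length 3 (low, mixed, high)")
  }
  clinical_vars <- c("age", "histology", "figo", "grade", "peritoneal",
                     "residual")
  known <- c(genes, clinical_vars)
  for (nm in list(names(beta_true_survival), names(beta_true_response))) {
    bad <- setdiff(nm, known)
    if (length(bad))
      stop("beta coefficients refer to unknown variables: ",
           paste(bad, collapse = ", "))
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (censoring_window[1] <= 0 || censoring_window[2] <= censoring_window[1])
    stop("censoring_window must be 0 < c_min < c_max")
  if (weibull_shape <= 0 || weibull_scale <= 0 || weibull_scale_pfs <= 0)
    stop("Weibull parameters must be positive")
  structure(list(
    n_samples = as.integer(n_samples),
    subtype_proportions = setNames(as.numeric(subtype_proportions),
                                   c("low", "mixed", "high")),
    gene_blocks = gene_blocks, noise_sd = noise_sd,
    beta_true_survival = beta_true_survival,
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    weibull_scale_pfs = weibull_scale_pfs,
    censoring_window = as.numeric(censoring_window),
    beta_true_response = beta_true_response,
    response_intercept = response_intercept,
    missing_rate = missing_rate,
    clinical_marginals = clinical_marginals,
    seed = as.integer(seed)), class = "synthetic_config")
}

# exchangeable-correlation multivariate normal block, n x m
rmvn_exchangeable <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), n, m)
  if (m == 1 || rho == 0) return(z)
  # X = sqrt(rho)*shared + sqrt(1-rho)*own has cor rho (rho >= 0); for
  # negative rho use the eigen square root of the exchangeable matrix
  if (rho > 0) {
    shared <- rnorm(n)
    sqrt(rho) * shared + sqrt(1 - rho) * z
  } else {
    sigma <- matrix(rho, m, m)
    diag(sigma) <- 1
    e <- eigen(sigma, symmetric = TRUE)
    z %*% (e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
  }
}

#' Generate a synthetic signature-profiling cohort
#'
#' Draws a full cohort from a [synthetic_config]: log2 expression with
#' block-exchangeable correlation and subtype mean shifts, clinical
#' covariates from the configured marginals, right-censored Weibull overall
#' and progression-free survival driven by the configured log-hazard
#' coefficients, a Bernoulli treatment response from the logistic model, and
#' optional MCAR missingness. Generation is a pure function of the
#' configuration (including its seed).
#'
#' @param config a [synthetic_config].
#' @return A `cohort` object: list with `expression` (log2
#'   [expression_matrix]), `clinical` (data frame with sample_id, os/pfs
#'   time and event, response, and the six clinicopathological covariates),
#'   `true_subtype` (factor, per sample), `signature`, and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  cm <- config$clinical_marginals
  with_seed(config$seed, {
    sample_id <- sprintf("S%03d", seq_len(n))
    subtype <- factor(
      sample(c("immune_low", "mixed", "immune_high"), n, replace = TRUE,
             prob = config$subtype_proportions),
      levels = c("immune_low", "mixed", "immune_high"))
    sub_idx <- as.integer(subtype) # 1 = low, 2 = mixed, 3 = high

    genes <- unlist(lapply(config$gene_blocks, `[[`, "genes"))
    expr <- matrix(NA_real_, n, length(genes),
                   dimnames = list(sample_id, genes))
    for (b in config$gene_blocks) {
      m <- length(b$genes)
      block <- rmvn_exchangeable(n, m, b$rho)
      block <- block + b$shift[sub_idx]
      expr[, b$genes] <- block
    }
    if (config$noise_sd > 0)
      expr <- expr + matrix(rnorm(n * length(genes), sd = config$noise_sd),
                            n, length(genes))

    age <- pmin(pmax(round(rnorm(n, cm$age_mean, cm$age_sd)),
                     cm$age_range[1]), cm$age_range[2])
    histology <- rbinom(n, 1, cm$p_serous)          # 1 = serous
    figo <- sample(0:2, n, replace = TRUE, prob = cm$p_figo) # II/III/IV
    grade <- rbinom(n, 1, cm$p_grade3)              # 1 = G3
    peritoneal <- rbinom(n, 1, cm$p_peritoneal)
    residual <- sample(0:2, n, replace = TRUE, prob = cm$p_residual)
    clin_design <- cbind(age = age, histology = histology, figo = figo,
                         grade = grade, peritoneal = peritoneal,
                         residual = residual)

    design <- cbind(expr, clin_design)
    lp <- linear_predictor(design, config$beta_true_survival)
    lp <- lp - mean(lp)

    u_os <- runif(n)
    t_os <- config$weibull_scale *
      (-log(u_os) * exp(-lp))^(1 / config$weibull_shape)
    u_pfs <- runif(n)
    t_pfs_raw <- config$weibull_scale_pfs *
      (-log(u_pfs) * exp(-lp))^(1 / config$weibull_shape)
    t_pfs <- pmin(t_pfs_raw, t_os) # progression precedes or coincides with death
    cens <- runif(n, config$censoring_window[1], config$censoring_window[2])
    os_time <- pmin(t_os, cens)
    os_event <- as.integer(t_os <= cens)
    pfs_time <- pmin(t_pfs, cens)
    pfs_event <- as.integer(t_pfs <= cens)

    lp_resp <- linear_predictor(design, config$beta_true_response)
    lp_resp <- lp_resp - mean(lp_resp)
    response <- rbinom(n, 1, plogis(config$response_intercept + lp_resp))

    clinical <- data.frame(
      sample_id = sample_id,
      os_time = os_time, os_event = os_event,
      pfs_time = pfs_time, pfs_event = pfs_event,
      response = response,
      age = age, histology = histology, figo = figo, grade = grade,
      peritoneal = peritoneal, residual = residual,
      stringsAsFactors = FALSE)

    em <- expression_matrix(expr, scale = "log2")
    if (config$missing_rate > 0)
      em <- inject_missing(em, config$missing_rate,
                           seed = config$seed + 104729L)
    structure(list(expression = em, clinical = clinical,
                   true_subtype = setNames(subtype, sample_id),
                   signature = default_signature(), config = config),
              class = "cohort")
  })
}

linear_predictor <- function(design, beta) {
  if (!length(beta)) return(rep(0, nrow(design)))
  as.vector(design[, names(beta), drop = FALSE] %*% beta)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: n = %d, %d genes; OS events %.1f%%, responders %.1f%%\n",
    nrow(x$expression), ncol(x$expression),
    100 * mean(x$clinical$os_event), 100 * mean(x$clinical$response)))
  print(table(x$true_subtype))
  invisible(x)
}

#' Inject missing-completely-at-random cells
#'
#' Sets each cell of an expression matrix to `NA` independently with the
#' given probability; the input matrix is not modified.
#'
#' @param expr an [expression_matrix].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed; the same seed reproduces the same mask.
#' @return A new [expression_matrix] with missing cells.
#' @export
inject_missing <- function(expr, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(expr)
  x <- as_plain_matrix(expr)
  with_seed(seed, {
    mask <- matrix(runif(length(x)) < rate, nrow(x), ncol(x))
    x[mask] <- NA_real_
  })
  expression_matrix(x, scale = expr_scale(expr))
}

#' Emit a Ct-level qPCR table reproducing a given expression matrix
#'
#' Constructs cycle-threshold data whose delta-delta-Ct normalisation
#' recovers the given log2 expression matrix exactly:
#' `Ct[g, s] = ct_reference - log2_expression[g, s]`, housekeeping genes at a
#' constant Ct, plus a calibrator row at `ct_reference` for every gene.
#' Optional gaussian measurement noise can be added to the gene Ct values
#' (the round trip is then only approximate).
#'
#' @param expr a log2-scale [expression_matrix] without missing values.
#' @param ct_reference calibrator Ct (cycles) assigned to every gene.
#' @param hkg_ct constant Ct of the housekeeping genes.
#' @param noise_sd gaussian noise SD on the emitted gene Ct values (cycles).
#' @param seed seed for the measurement noise.
#' @param calibrator_id row name of the emitted calibrator sample.
#' @return A [ct_table].
#' @export
emit_ct_table <- function(expr, ct_reference = 22, hkg_ct = 18,
                          noise_sd = 0, seed = 1,
                          calibrator_id = "CALIBRATOR") {
  if (expr_scale(expr) != "log2") stop("expr must be on log2 scale")
  if (any(is.na(expr))) stop("expr must not contain missing values")
  if (calibrator_id %in% rownames(expr))
    stop("calibrator id collides with a sample id")
  hkg <- default_signature()$hkg
  x <- as_plain_matrix(expr)
  ct_goi <- ct_reference - x
  if (noise_sd > 0)
    ct_goi <- ct_goi + with_seed(seed,
      matrix(rnorm(length(ct_goi), sd = noise_sd), nrow(ct_goi)))
  ct <- cbind(ct_goi, matrix(hkg_ct, nrow(x), length(hkg),
                             dimnames = list(rownames(x), hkg)))
  cal <- c(rep(ct_reference, ncol(x)), rep(hkg_ct, length(hkg)))
  ct <- rbind(ct, setNames(cal, colnames(ct)))
  rownames(ct)[nrow(ct)] <- calibrator_id
  ct_table(ct, hkg_genes = hkg, calibrator_id = calibrator_id)
}

#' Write / read a cohort as plain-text files
#'
#' Writes the expression matrix and clinical table as TSV plus a JSON sidecar
#' recording the full generator configuration.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns a
#'   `cohort` (without `true_subtype` unless the labels file is present).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$true_subtype))
    write.table(data.frame(sample_id = names(cohort$true_subtype),
                           true_subtype = as.character(cohort$true_subtype)),
                file.path(dir, "true_subtype.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @param dir directory written by `write_cohort`.
#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  expr <- read_expression_tsv(file.path(dir, "expression.tsv"), scale = "log2")
  clinical <- read.delim(file.path(dir, "clinical.tsv"),
                         stringsAsFactors = FALSE)
  subtype <- NULL
  stf <- file.path(dir, "true_subtype.tsv")
  if (file.exists(stf)) {
    df <- read.delim(stf, stringsAsFactors = FALSE)
    subtype <- setNames(factor(df$true_subtype,
                               levels = c("immune_low", "mixed",
                                          "immune_high")),
                        df$sample_id)
  }
  stopifnot(identical(rownames(expr), clinical$sample_id))
  structure(list(expression = expr, clinical = clinical,
                 true_subtype = subtype, signature = default_signature(),
                 config = NULL),
            class = "cohort")
}
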