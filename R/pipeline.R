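#' Run the full analysis sequence on a cohort
#'
#' Executes the complete pipeline on a cohort (synthetic or read from
#' files): imputation if the expression matrix has missing cells, gene-gene
#' correlation, immune-subtype stratification with per-gene group
#' comparisons and the response association, the seven penalized Cox model
#' specifications validated by outer leave-one-out cross-validation (PEV,
#' c-index, global p, added value over the clinical model), the importance
#' table of the combined model, and quartile risk groups with Kaplan-Meier
#' log-rank testing for the best model.
#'
#' The model-validation stage is the expensive part (an inner LOO penalty
#' selection nested in an outer LOO loop, per specification); restrict
#' `models` for quick runs.
#'
#' @param cohort a `cohort` object ([generate_cohort()] / [read_cohort()]).
#' @param outcome `"os"` or `"pfs"`.
#' @param penalty `"ridge"` or `"lasso"`.
#' @param models character vector of model names (subset of
#'   [model_variable_sets()] names) or `"all"`.
#' @param k,min_separation subtype-assignment parameters.
#' @param impute_seed seed for the imputation stage.
#' @return A `run_report` list with stages `preprocess`, `stratification`,
#'   `models` (Table-2-style data frame), `importance`, `risk_groups`, and
#'   `provenance`.
#' @export
run_full_analysis <- function(cohort, outcome = c("os", "pfs"),
                              penalty = c("ridge", "lasso"),
                              models = "all", k = 3, min_separation = 2,
                              impute_seed = 1) {
  outcome <- match.arg(outcome)
  penalty <- match.arg(penalty)
  specs <- model_variable_sets(cohort$signature)
  if (!identical(models, "all")) {
    bad <- setdiff(models, names(specs))
    if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
    specs <- specs[models]
  }
  expr <- cohort$expression
  n_missing <- sum(is.na(expr))
  if (n_missing > 0) expr <- impute_chained(expr, seed = impute_seed)
  cohort$expression <- expr
  time <- cohort$clinical[[paste0(outcome, "_time")]]
  event <- cohort$clinical[[paste0(outcome, "_event")]]

  corr <- correlation_matrix(expr)
  subtypes <- assign_subtypes(expr, cohort$signature, k = k,
                              min_separation = min_separation)
  two_groups <- subtypes$labels %in% c("immune_low", "immune_high")
  comparison <- NULL
  response_assoc <- NULL
  if (sum(two_groups) >= 4 &&
      nlevels(droplevels(subtypes$labels[two_groups])) == 2) {
    comparison <- compare_groups(
      expression_matrix(as_plain_matrix(expr)[two_groups, , drop = FALSE],
                        "log2"),
      droplevels(subtypes$labels[two_groups]))
    tab <- table(subtypes$labels[two_groups],
                 cohort$clinical$response[two_groups])
    if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
        all(colSums(tab) > 0))
      response_assoc <- chi_square_2xk(tab)
  }

  eta_by_model <- list()
  rows <- list()
  for (nm in names(specs)) {
    D <- build_design(cohort, specs[[nm]])
    cv <- loocv_predictors(D, time, event, penalty = penalty)
    eta_by_model[[nm]] <- cv$eta
    rep_ <- performance_report(cv$eta, time, event,
                               eta_clinical = if (nm != "Clinics")
                                 eta_by_model[["Clinics"]] else NULL)
    rows[[nm]] <- data.frame(model = nm, pev_pct = 100 * rep_$pev,
                             c_index = rep_$c_index,
                             global_p = rep_$global_p,
                             added_value_p = rep_$added_value_p,
                             stringsAsFactors = FALSE)
  }
  model_table <- do.call(rbind, rows)
  rownames(model_table) <- NULL

  combined <- names(specs)[length(specs)]
  D <- build_design(cohort, specs[[combined]])
  path <- select_lambda_loocv(D, time, event, penalty = penalty)
  fit <- cox_penalized(D, time, event, penalty = penalty,
                       lambda = path$lambda_min)
  importance <- importance_s36(fit)
  risk <- risk_groups_km(eta_by_model[[combined]], time, event)

  structure(list(
    preprocess = list(n_samples = nrow(expr), n_genes = ncol(expr),
                      n_imputed = n_missing),
    stratification = list(
      subtype_sizes = as.list(table(subtypes$labels)),
      cluster_core_means = as.list(subtypes$cluster_core_means),
      n_significant_genes = if (is.null(comparison)) NA_integer_
                            else sum(comparison$table$p_holm < 0.05),
      response_chisq = response_assoc),
    correlation = list(
      n_strong_pairs = sum(corr$r[upper.tri(corr$r)] > 0.5 &
                           corr$p_adj[upper.tri(corr$p_adj)] < 0.001,
                           na.rm = TRUE)),
    models = model_table,
    importance = importance,
    risk_groups = list(
      thresholds = as.list(risk$thresholds),
      sizes = as.list(table(risk$group)),
      logrank = risk$logrank),
    eta = eta_by_model,
    provenance = list(outcome = outcome, penalty = penalty,
                      models = names(specs),
                      seed = cohort$config$seed %||% NA)),
    class = "run_report")
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_full_analysis()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$eta <- lapply(out$eta, function(e) as.list(setNames(e, names(e))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report (", x$provenance$outcome, ", ", x$provenance$penalty,
      ")\n", sep = "")
  cat("subtypes:", paste(names(x$stratification$subtype_sizes),
                         unlist(x$stratification$subtype_sizes),
                         sep = "=", collapse = ", "), "\n")
  print(x$models, digits = 3)
  invisible(x)
}
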