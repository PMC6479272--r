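#' Ct table container
#'
#' Cycle-threshold (Ct) values from real-time qPCR: one row per sample
#' (including the calibrator sample), one column per assayed gene, with the
#' housekeeping genes among the columns.
#'
#' @param ct numeric matrix of Ct values (cycles), rownames = sample ids.
#' @param hkg_genes housekeeping gene column names used as the normalisation
#'   reference.
#' @param calibrator_id row name of the calibrator sample.
#' @return A `ct_table` object.
#' @export
ct_table <- function(ct, hkg_genes, calibrator_id) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix needs sample rownames and gene colnames")
  missing_hkg <- setdiff(hkg_genes, colnames(ct))
  if (length(missing_hkg))
    stop("housekeeping genes absent from ct table: ",
         paste(missing_hkg, collapse = ", "))
  if (!calibrator_id %in% rownames(ct))
    stop("calibrator sample '", calibrator_id, "' absent from ct table")
  if (any(!is.finite(ct) & !is.na(ct)))
    stop("Ct values must be finite where present")
  structure(list(ct = ct, hkg_genes = as.character(hkg_genes),
                 calibrator_id = as.character(calibrator_id)),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("Ct table: %d samples x %d genes (%d HKG), calibrator '%s'\n",
              nrow(x$ct), ncol(x$ct), length(x$hkg_genes), x$calibrator_id))
  invisible(x)
}

#' Delta-delta-Ct normalisation of qPCR data
#'
#' Converts Ct values to relative expression: each gene's Ct is normalised to
#' the mean Ct of the housekeeping genes within the same sample (the
#' arithmetic mean on the Ct scale equals the geometric mean of the linear
#' quantities), then expressed relative to the calibrator sample and
#' exponentiated base 2:
#' \deqn{R_{g,s} = 2^{-(\Delta Ct_{g,s} - \Delta Ct_{g,cal})},\quad
#'       \Delta Ct_{g,s} = Ct_{g,s} - \overline{Ct}_{HKG,s}.}
#' Amplification efficiency is fixed at 2. Housekeeping columns are dropped
#' from the output; the calibrator row is retained (with R = 1 for every
#' gene).
#'
#' @param ct a [ct_table]. The calibrator row must be complete for all genes
#'   and housekeeping genes. A sample with a missing housekeeping Ct gets
#'   `NA` for all its genes (with a warning).
#' @return A linear-scale [expression_matrix].
#' @export
normalize_qpcr <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  m <- ct$ct
  goi <- setdiff(colnames(m), ct$hkg_genes)
  if (!length(goi)) stop("no genes of interest beyond the housekeeping genes")
  cal <- m[ct$calibrator_id, , drop = TRUE]
  bad_cal <- names(cal)[is.na(cal)]
  if (length(bad_cal))
    stop("calibrator sample has missing Ct for gene(s): ",
         paste(bad_cal, collapse = ", "))
  hkg_mean <- rowMeans(m[, ct$hkg_genes, drop = FALSE])
  flagged <- rownames(m)[is.na(hkg_mean)]
  if (length(flagged))
    warning("missing housekeeping Ct; sample(s) flagged with NA output: ",
            paste(flagged, collapse = ", "))
  dct <- m[, goi, drop = FALSE] - hkg_mean
  ddct <- sweep(dct, 2, dct[ct$calibrator_id, ], "-")
  expression_matrix(2^(-ddct), scale = "linear")
}

#' Log2 transform of a linear-scale expression matrix
#'
#' @param expr a linear-scale [expression_matrix] with strictly positive
#'   values where present. An already log2-scaled matrix is rejected.
#' @return The matrix on log2 scale; missing entries preserved.
#' @export
log2_transform <- function(expr) {
  if (expr_scale(expr) != "linear")
    stop("input is already on log2 scale")
  bad <- which(expr <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive expression values at: ",
         paste(sprintf("[%s, %s]", rownames(expr)[bad[, 1]],
                       colnames(expr)[bad[, 2]]), collapse = ", "))
  expression_matrix(log2(as_plain_matrix(expr)), scale = "log2")
}

#' Chained-equations imputation with predictive mean matching
#'
#' Completes a log2-scale expression matrix by chained equations: missing
#' cells are initialised with column means; then for a fixed number of
#' cycles, each column with missingness is in turn regressed (least squares)
#' on all other columns using its observed entries, and its missing entries
#' are imputed by predictive mean matching — the predicted value is replaced
#' by the observed value of one of the `k_donors` donors whose predictions
#' lie closest. A single completed matrix is returned (the downstream models
#' consume one completed data set); observed cells are never modified.
#'
#' @param expr a log2-scale [expression_matrix]; every column must be less
#'   than half missing and no column may be entirely missing.
#' @param n_cycles number of sweeps over the columns.
#' @param k_donors donor pool size for predictive mean matching.
#' @param seed integer seed making the donor draws deterministic.
#' @return The completed [expression_matrix] (no missing cells).
#' @export
impute_chained <- function(expr, n_cycles = 10, k_donors = 5, seed = 1) {
  if (expr_scale(expr) != "log2")
    stop("imputation operates on the log2 scale")
  x <- as_plain_matrix(expr)
  miss <- is.na(x)
  if (!any(miss)) return(expr)
  frac <- colMeans(miss)
  if (any(frac == 1))
    stop("column(s) entirely missing: ",
         paste(colnames(x)[frac == 1], collapse = ", "))
  if (any(frac >= 0.5))
    stop("column(s) at least half missing: ",
         paste(colnames(x)[frac >= 0.5], collapse = ", "))
  with_seed(seed, {
    # mean initialisation
    for (j in which(frac > 0))
      x[miss[, j], j] <- mean(x[, j], na.rm = TRUE)
    cols <- which(frac > 0)
    for (cycle in seq_len(n_cycles)) {
      for (j in cols) {
        obs <- !miss[, j]
        df <- data.frame(y = x[, j], x[, -j, drop = FALSE])
        fit <- lm(y ~ ., data = df[obs, , drop = FALSE])
        pred <- predict_lm_safe(fit, df)
        yhat_obs <- pred[obs]
        yhat_mis <- pred[!obs]
        yobs <- x[obs, j]
        for (ii in seq_along(yhat_mis)) {
          d <- abs(yhat_obs - yhat_mis[ii])
          donors <- order(d)[seq_len(min(k_donors, length(d)))]
          pick <- donors[sample.int(length(donors), 1L)]
          x[which(!obs)[ii], j] <- yobs[pick]
        }
      }
    }
  })
  expression_matrix(x, scale = "log2")
}

# predict() that tolerates rank-deficient fits without warnings
predict_lm_safe <- function(fit, newdata) {
  suppressWarnings(unname(predict(fit, newdata = newdata)))
}
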