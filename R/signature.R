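#' Gene signature definition
#'
#' A gene signature pairs a set of genes of interest, each assigned to a
#' category (`"sphingo_lpa"` for sphingolipid/lysophosphatidate-associated
#' genes, `"immune"` for immune lineage markers), with the housekeeping genes
#' used as the qPCR normalisation reference.
#'
#' @param symbols character vector of gene symbols.
#' @param categories character vector, same length, each `"sphingo_lpa"` or
#'   `"immune"`.
#' @param hkg character vector of housekeeping gene symbols.
#' @return An object of class `gene_signature`: a list with elements `genes`
#'   (data frame with columns `symbol`, `category`) and `hkg`.
#' @seealso [default_signature()]
#' @export
gene_signature <- function(symbols, categories, hkg) {
  stopifnot(length(symbols) == length(categories))
  if (anyDuplicated(symbols)) stop("duplicated gene symbols in signature")
  if (!all(categories %in% c("sphingo_lpa", "immune")))
    stop("categories must be 'sphingo_lpa' or 'immune'")
  structure(
    list(genes = data.frame(symbol = as.character(symbols),
                            category = as.character(categories),
                            stringsAsFactors = FALSE),
         hkg = as.character(hkg)),
    class = "gene_signature")
}

# The 38 sphingolipid/lysophosphatidate-associated genes: sphingomyelin /
# salvage pathway enzymes, S1P and LPA receptor families, and the CD1
# lipid-antigen-presentation molecules.
.sphingo_lpa_genes <- c(
  "SGPP1", "SGPP2", "PPAP2A", "PPAP2B", "PPAP2C", "SGPL1", "SPHK1", "SPHK2",
  "ENPP2", "SMPD1", "SMPD2", "SMPD3",
  "CERS1", "CERS2", "CERS3", "CERS4", "CERS5", "CERS6",
  "ASAH1", "NAAA", "CERK", "SGMS1", "SGMS2", "UGT8", "UGCG",
  "S1PR1", "S1PR2", "S1PR3", "S1PR4", "S1PR5",
  "LPAR1", "LPAR2", "LPAR3", "LPAR4", "LPAR5", "LPAR6",
  "CD1B", "CD1D")

# The 8 immune lineage markers: B cell (MS4A1/CD20, IGHG1, IGHM),
# monocyte/macrophage (CD14, CD68, CD163), T cell (CD3E), pan-leukocyte
# (PTPRC/CD45).
.immune_genes <- c("MS4A1", "IGHG1", "IGHM", "CD14", "CD68", "CD163",
                   "CD3E", "PTPRC")

.hkg_genes <- c("ACTB", "TOP1", "UBC", "YWHAZ")

#' Default 38/8-gene sphingolipid/lysophosphatidate/immune signature
#'
#' The default signature used throughout the package: 38
#' sphingolipid/lysophosphatidate-associated genes plus 8 immune lineage
#' markers (46 expression variables per sample), normalised against the
#' housekeeping genes ACTB, TOP1, UBC and YWHAZ.
#'
#' @return A [gene_signature] object.
#' @examples
#' sig <- default_signature()
#' table(sig$genes$category)
#' @export
default_signature <- function() {
  gene_signature(
    symbols = c(.sphingo_lpa_genes, .immune_genes),
    categories = c(rep("sphingo_lpa", length(.sphingo_lpa_genes)),
                   rep("immune", length(.immune_genes))),
    hkg = .hkg_genes)
}

#' Immune-core gene set used for subtype labelling
#'
#' The ten genes that drive the immune-low/high separation: the 8 immune
#' lineage markers plus the two sphingolipid-associated genes (S1PR4, CD1B)
#' that co-cluster with them.
#'
#' @param signature a [gene_signature].
#' @return Character vector of gene symbols.
#' @export
immune_core_genes <- function(signature = default_signature()) {
  core <- c(signature$genes$symbol[signature$genes$category == "immune"],
            "S1PR4", "CD1B")
  intersect(core, signature$genes$symbol)
}

#' @export
print.gene_signature <- function(x, ...) {
  tab <- table(x$genes$category)
  cat("Gene signature:", nrow(x$genes), "genes (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "); HKG:", paste(x$hkg, collapse = ", "), "\n")
  invisible(x)
}
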