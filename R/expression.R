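#' @include containers.R
NULL

#' Collapse duplicate gene symbols in an expression matrix
#'
#' Rows whose values are all zero are dropped; then, for each gene symbol
#' mapped by multiple Ensembl identifiers, only the row with the maximum
#' mean value across samples is kept, ties broken by lexicographic
#' Ensembl id. The result has unique symbols as row names.
#'
#' @param mat numeric matrix (genes x samples), TPM/FPKM/expected counts.
#' @param ensembl character vector of Ensembl ids, one per row.
#' @param symbol character vector of gene symbols, one per row.
#' @return numeric matrix with unique symbols as rownames.
#' @export
collapseToSymbol <- function(mat, ensembl, symbol) {
  stopifnot(nrow(mat) == length(ensembl), nrow(mat) == length(symbol))
  nz <- rowSums(mat) > 0
  mat <- mat[nz, , drop = FALSE]
  ensembl <- ensembl[nz]
  symbol <- symbol[nz]
  if (!nrow(mat)) {
    rownames(mat) <- character()
    return(mat)
  }
  means <- rowMeans(mat)
  ord <- order(symbol, -means, ensembl, method = "radix")
  keep <- ord[!duplicated(symbol[ord])]
  keep <- sort(keep)
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- symbol[keep]
  out
}

#' Within-cohort expression z-scores
#'
#' Values are log2(x + 1)-transformed and standardized per gene within
#' each cohort group (typically cancer group x RNA library type, to avoid
#' library-preparation batch effects): z = (value - mean) / sd with the
#' population (divide-by-n) standard deviation. Constant genes (sd = 0)
#' and single-sample cohorts get z = 0.
#'
#' @param mat numeric matrix (genes x samples), raw TPM/FPKM.
#' @param grouping character/factor of cohort labels, one per column;
#'   default a single cohort.
#' @return numeric matrix of z-scores, same dimensions as `mat`.
#' @export
cohortZscore <- function(mat, grouping = rep("all", ncol(mat))) {
  stopifnot(ncol(mat) == length(grouping))
  lg <- log2(mat + 1)
  z <- lg
  for (g in unique(grouping)) {
    cols <- which(grouping == g)
    sub <- lg[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdpop <- sqrt(rowMeans((sub - mu)^2))
    zs <- (sub - mu) / ifelse(sdpop == 0, Inf, sdpop)
    z[, cols] <- zs
  }
  z
}

#' Over-/under-expression flags from z-scores
#'
#' Over-expression fires at z >= `zscore_high` (default 2, boundary
#' included); under-expression fires at z < `zscore_low` (default -2,
#' strict — the boundary does not fire).
#'
#' @param zscores z-score matrix from [cohortZscore()].
#' @param gene gene symbol (must be a rowname of `zscores`).
#' @param direction `"over"` or `"under"`.
#' @param thresholds see [defaultThresholds()].
#' @return named logical vector, one per sample; all-`FALSE` when the
#'   gene is absent from the matrix.
#' @export
expressionFlag <- function(zscores, gene, direction = c("over", "under"),
                           thresholds = defaultThresholds()) {
  direction <- match.arg(direction)
  if (!gene %in% rownames(zscores)) {
    out <- rep(FALSE, ncol(zscores))
    names(out) <- colnames(zscores)
    return(out)
  }
  z <- zscores[gene, ]
  if (direction == "over") z >= thresholds$zscore_high
  else z < thresholds$zscore_low
}

#' Read a gene-by-sample expression TSV
#'
#' First two columns are `ensembl_id` and `gene_symbol`; remaining columns
#' are samples.
#'
#' @param path TSV file.
#' @return list with `mat` (numeric matrix), `ensembl`, `symbol`.
#' @export
readExpression <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(mat) <- "double"
  list(mat = mat, ensembl = as.character(df[[1]]),
       symbol = as.character(df[[2]]))
}
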