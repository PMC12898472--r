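## Two-criterion drug-sensitivity screen over a sample-by-drug AUC table:
## differential AUC between risk groups (log2 fold change oriented so that
## lower AUC in the high-risk group is positive) and negative correlation of
## risk-gene expression with drug AUC.

#' Per-drug log2 fold change of AUC between risk groups
#'
#' `log2(mean AUC in low risk / mean AUC in high risk)`: positive values mean
#' the high-risk group has lower AUC, i.e. is more sensitive to the drug.
#'
#' @param auc samples x drugs AUC matrix (all values > 0).
#' @param groups factor per sample with levels `low`, `high`, both nonempty.
#' @return named numeric vector, one value per drug.
#' @export
aucLog2fc <- function(auc, groups) {
  auc <- .assertMatrix(auc, "AUC table")
  if (any(auc <= 0)) stop("AUC values must be strictly positive")
  groups <- factor(as.character(groups), levels = c("low", "high"))
  stopifnot(length(groups) == nrow(auc))
  if (any(table(groups) == 0)) stop("both risk groups must be nonempty")
  lowMean <- colMeans(auc[groups == "low", , drop = FALSE])
  highMean <- colMeans(auc[groups == "high", , drop = FALSE])
  log2(lowMean / highMean)
}

#' Risk-gene vs drug-AUC correlations
#'
#' Pearson (or Spearman) correlation between each risk gene's expression and
#' each drug's AUC over the shared samples, plus a per-drug aggregate
#' (`mean`, `median`, or `any` = the minimum, so that a single strongly
#' negative gene can pass the screen).
#'
#' @param expr genes x samples expression matrix.
#' @param auc samples x drugs AUC matrix.
#' @param riskGenes gene IDs to correlate (must be rows of `expr`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param aggregate `"mean"` (default), `"median"` or `"any"`.
#' @return list with `r` (genes x drugs correlation matrix) and `aggregate_r`
#'   (named per-drug numeric).
#' @export
geneAucCorrelation <- function(expr, auc, riskGenes,
                               method = c("pearson", "spearman"),
                               aggregate = c("mean", "median", "any")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  expr <- .assertMatrix(expr)
  auc <- .assertMatrix(auc, "AUC table")
  missing <- setdiff(riskGenes, rownames(expr))
  if (length(missing))
    stop("risk genes absent from the matrix: ", paste(missing, collapse = ", "))
  shared <- intersect(colnames(expr), rownames(auc))
  if (length(shared) < 3L)
    stop("need at least 3 samples shared between expression and AUC tables")
  e <- expr[riskGenes, shared, drop = FALSE]
  a <- auc[shared, , drop = FALSE]
  r <- matrix(NA_real_, length(riskGenes), ncol(a),
              dimnames = list(riskGenes, colnames(a)))
  for (g in riskGenes) {
    for (d in colnames(a)) {
      x <- e[g, ]; y <- a[, d]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("zero-variance column for ", g, " ~ ", d, "; r set to 0")
        r[g, d] <- 0
      } else {
        r[g, d] <- stats::cor(x, y, method = method)
      }
    }
  }
  agg <- switch(aggregate,
                mean = colMeans(r),
                median = apply(r, 2, stats::median),
                any = apply(r, 2, min))
  list(r = r, aggregate_r = agg)
}

#' Two-criterion drug-sensitivity screen
#'
#' A drug passes when its AUC log2 fold change between risk groups is
#' positive (lower AUC in high risk) and the aggregated risk-gene correlation
#' with its AUC is below -0.05. Results are sorted by log2 fold change,
#' descending.
#'
#' @param auc samples x drugs AUC matrix.
#' @param groups per-sample risk group factor (`low`/`high`), named by sample
#'   or aligned with `expr` columns.
#' @param expr genes x samples expression matrix.
#' @param riskGenes risk-model gene panel.
#' @param source source tag recorded per drug (default `"synthetic"`).
#' @param method,aggregate correlation options (see [geneAucCorrelation()]).
#' @return a [DrugScreen].
#' @export
screenDrugs <- function(auc, groups, expr, riskGenes, source = "synthetic",
                        method = c("pearson", "spearman"),
                        aggregate = c("mean", "median", "any")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  auc <- .assertMatrix(auc, "AUC table")
  expr <- .assertMatrix(expr)
  if (is.null(names(groups))) names(groups) <- colnames(expr)
  shared <- intersect(colnames(expr), rownames(auc))
  if (!length(shared)) stop("no shared samples between expression and AUC")
  aucS <- auc[shared, , drop = FALSE]
  grpS <- factor(as.character(groups[shared]), levels = c("low", "high"))
  lfc <- aucLog2fc(aucS, grpS)
  corr <- geneAucCorrelation(expr[, shared, drop = FALSE], aucS, riskGenes,
                             method = method, aggregate = aggregate)
  ord <- order(-lfc, names(lfc))
  res <- DataFrame(
    drug_id = names(lfc)[ord],
    source = source,
    log2fc_auc = unname(lfc[ord]),
    aggregate_r = unname(corr$aggregate_r[names(lfc)[ord]]),
    row.names = names(lfc)[ord]
  )
  res$passes <- res$log2fc_auc > 0 & res$aggregate_r < -0.05
  methods::new("DrugScreen", results = res,
               geneCorrelations = corr$r[, res$drug_id, drop = FALSE],
               aggregate = aggregate)
}
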