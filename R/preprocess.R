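#' Quality-control filtering of cells and genes
#'
#' Removes low-quality cells (fewer than `minGenes` detected genes, or a
#' mitochondrial count fraction above `maxMito`), then genes expressed in
#' fewer than `minCells` of the surviving cells. Mitochondrial genes are
#' identified by an ID prefix. Survivor order is preserved, and the filter is
#' idempotent.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay, or a genes x cells count matrix.
#' @param minGenes minimum detected genes per cell (default 200).
#' @param maxMito maximum mitochondrial count fraction per cell (default 0.20).
#' @param minCells minimum cells a gene must be detected in (default 3).
#' @param mitoPrefix gene-ID prefix marking mitochondrial genes.
#' @param ... passed between methods.
#' @return filtered object of the same class as `x`.
#' @export
setGeneric("qcFilter", function(x, ...) standardGeneric("qcFilter"))

.qcFilterMatrix <- function(counts, minGenes, maxMito, minCells, mitoPrefix) {
  counts <- .assertCounts(counts)
  detected <- colSums(counts > 0)
  mito <- startsWith(rownames(counts), mitoPrefix)
  tot <- colSums(counts)
  mitoFrac <- ifelse(tot > 0, colSums(counts[mito, , drop = FALSE]) / tot, 0)
  keepCells <- detected >= minGenes & mitoFrac <= maxMito
  if (!any(keepCells)) stop("QC removed every cell")
  kept <- counts[, keepCells, drop = FALSE]
  keepGenes <- rowSums(kept > 0) >= minCells
  if (!any(keepGenes)) stop("QC removed every gene")
  kept[keepGenes, , drop = FALSE]
}

#' @rdname qcFilter
#' @export
setMethod("qcFilter", "matrix",
  function(x, minGenes = 200, maxMito = 0.20, minCells = 3,
           mitoPrefix = "MT-", ...) {
    .qcFilterMatrix(x, minGenes, maxMito, minCells, mitoPrefix)
  })

#' @rdname qcFilter
#' @export
setMethod("qcFilter", "SingleCellExperiment",
  function(x, minGenes = 200, maxMito = 0.20, minCells = 3,
           mitoPrefix = "MT-", ...) {
    counts <- .getAssay(x, "counts")
    kept <- .qcFilterMatrix(counts, minGenes, maxMito, minCells, mitoPrefix)
    x[rownames(kept), colnames(kept)]
  })

#' Library-size log-normalization
#'
#' Per cell: `ln(1 + scale * x / colsum)` with the natural logarithm
#' (the output records the log base in its metadata).
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay, or a genes x cells count matrix.
#' @param scale library-size scale factor (default 10,000).
#' @param ... passed between methods.
#' @return for an SCE, the object with a `lognorm` assay added; for a matrix,
#'   the normalized matrix.
#' @export
setGeneric("logNormalize", function(x, ...) standardGeneric("logNormalize"))

.logNormalizeMatrix <- function(counts, scale) {
  counts <- .assertCounts(counts)
  cs <- colSums(counts)
  if (any(cs == 0))
    stop("zero column sum for cell(s): ",
         paste(utils::head(colnames(counts)[cs == 0], 5), collapse = ", "))
  log1p(sweep(counts, 2, scale / cs, `*`))
}

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "matrix", function(x, scale = 1e4, ...) {
  .logNormalizeMatrix(x, scale)
})

#' @rdname logNormalize
#' @export
setMethod("logNormalize", "SingleCellExperiment", function(x, scale = 1e4, ...) {
  SummarizedExperiment::assay(x, "lognorm") <-
    .logNormalizeMatrix(.getAssay(x, "counts"), scale)
  S4Vectors::metadata(x)$lognorm <- list(scale = scale, base = exp(1))
  x
})

#' Select highly variable genes
#'
#' Ranks genes by variance-stabilized dispersion: log10 variance is regressed
#' on a polynomial in log10 mean, values are standardized by the fitted
#' (back-transformed) standard deviation and clipped at `sqrt(n_cells)`, and
#' genes are ranked by the variance of the clipped standardized values. Ties
#' are broken by gene ID.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a `lognorm`
#'   assay, or a genes x cells normalized matrix.
#' @param n number of genes to return (default 2000).
#' @param degree degree of the polynomial mean-variance fit (default 2).
#' @param ... passed between methods.
#' @return character vector of `n` gene IDs, ranked most variable first.
#' @export
setGeneric("selectHvg", function(x, ...) standardGeneric("selectHvg"))

.selectHvgMatrix <- function(mat, n, degree) {
  mat <- .assertMatrix(mat)
  if (n <= 0) stop("'n' must be positive")
  if (n > nrow(mat)) stop("'n' exceeds the number of genes")
  stat <- .hvgStatistic(mat, degree)
  ord <- order(-stat, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

## standardized-variance statistic; shared with tests' brute-force oracle only
## through its documented definition, not through code.
.hvgStatistic <- function(mat, degree = 2) {
  mu <- rowMeans(mat)
  v <- .rowVars(mat)
  stat <- rep(0, nrow(mat))
  usable <- v > 0 & mu > 0
  if (sum(usable) > degree + 1) {
    fit <- stats::lm(log10(v[usable]) ~ stats::poly(log10(mu[usable]), degree))
    esd <- sqrt(10^stats::fitted(fit))
    z <- (mat[usable, , drop = FALSE] - mu[usable]) / esd
    z <- pmin(z, sqrt(ncol(mat)))
    stat[usable] <- .rowVars(z)
  } else {
    stat[usable] <- v[usable]
  }
  names(stat) <- rownames(mat)
  stat
}

#' @rdname selectHvg
#' @export
setMethod("selectHvg", "matrix", function(x, n = 2000, degree = 2, ...) {
  .selectHvgMatrix(x, n, degree)
})

#' @rdname selectHvg
#' @export
setMethod("selectHvg", "SingleCellExperiment",
  function(x, n = 2000, degree = 2, ...) {
    .selectHvgMatrix(.getAssay(x, "lognorm"), n, degree)
  })
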