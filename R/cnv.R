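## Sliding-window CNV inference and malignant-cell classification.
##
## The signal chain is: filter uninformative genes -> per-gene z-score with
## clamping -> chromosome-sorted sliding-window smoothing with per-cell
## centering -> per-gene reference-cell adjustment -> per-cell MS (mean
## square) and CORR (correlation with the mean profile of the top-MS cells)
## -> threshold classification.

#' Filter genes uninformative for CNV inference
#'
#' Drops genes detected in fewer than `minCells` cells or with mean log2
#' expression below `minMeanLog2`. Input is natural-log normalized expression;
#' values are rescaled to the log2 scale for the mean-expression criterion.
#'
#' @param mat genes x cells normalized (natural-log) expression matrix.
#' @param minCells minimum cells with nonzero expression (default 10).
#' @param minMeanLog2 minimum mean log2 expression (default 0.1).
#' @return filtered matrix, original gene order preserved.
#' @export
cnvGeneFilter <- function(mat, minCells = 10, minMeanLog2 = 0.1) {
  mat <- .assertMatrix(mat)
  nzero <- rowSums(mat > 0)
  meanLog2 <- rowMeans(mat / log(2))
  keep <- nzero >= minCells & meanLog2 >= minMeanLog2
  if (!any(keep)) stop("no genes survive the CNV gene filter")
  mat[keep, , drop = FALSE]
}

#' Per-gene z-scoring with clamping
#'
#' Converts each gene's expression across cells to z-scores (sample standard
#' deviation, n-1) and clips them to `[-clamp, clamp]`. Zero-variance genes
#' are dropped with a warning.
#'
#' @param mat genes x cells expression matrix.
#' @param clamp symmetric clipping bound (default 3).
#' @return z-scored, clipped matrix (possibly fewer genes).
#' @export
zscoreClamp <- function(mat, clamp = 3) {
  mat <- .assertMatrix(mat)
  v <- .rowVars(mat)
  if (any(v == 0 | is.na(v))) {
    drop <- which(v == 0 | is.na(v))
    warning("dropping ", length(drop), " zero-variance gene(s)")
    mat <- mat[-drop, , drop = FALSE]
    v <- v[-drop]
  }
  z <- (mat - rowMeans(mat)) / sqrt(v)
  pmax(pmin(z, clamp), -clamp)
}

## window bounds for index i in a chromosome of length L, window width w:
## up to w genes centered on i, truncated at the chromosome boundary.
.windowBounds <- function(i, L, w) {
  lo <- max(1L, i - ((w - 1L) %/% 2L))
  hi <- min(L, i + (w %/% 2L))
  c(lo, hi)
}

#' Sliding-window smoothing of z-scored expression along chromosomes
#'
#' Genes are sorted by (chromosome, start); each gene's value is replaced by
#' the mean of the up-to-`w` genes in a window centered on it (windows are
#' truncated at chromosome boundaries, never spanning two chromosomes). The
#' smoothed profile is then centered per cell by subtracting the cell's
#' median (or mean) smoothed value.
#'
#' @param z genes x cells z-scored matrix (see [zscoreClamp()]).
#' @param annotation gene annotation with `gene_id`, `chromosome`, `start`
#'   covering every row of `z`.
#' @param w window width in genes (default 100).
#' @param centering per-cell centering: `"median"` (default), `"mean"` or
#'   `"none"`.
#' @return a [CnvProfile] (cells x genes, chromosome-sorted columns).
#' @export
smoothWindows <- function(z, annotation, w = 100,
                          centering = c("median", "mean", "none")) {
  centering <- match.arg(centering)
  z <- .assertMatrix(z)
  annotation <- DataFrame(annotation)
  key <- if ("gene_id" %in% colnames(annotation)) annotation$gene_id
         else rownames(annotation)
  missing <- setdiff(rownames(z), key)
  if (length(missing))
    stop("unannotated genes: ", paste(utils::head(missing, 10), collapse = ", "))
  ann <- annotation[match(rownames(z), key), , drop = FALSE]
  ord <- order(as.character(ann$chromosome), ann$start, rownames(z))
  z <- z[ord, , drop = FALSE]
  ann <- ann[ord, , drop = FALSE]

  smoothed <- matrix(NA_real_, nrow(z), ncol(z), dimnames = dimnames(z))
  chromFactor <- factor(as.character(ann$chromosome),
                        levels = unique(as.character(ann$chromosome)))
  for (ch in levels(chromFactor)) {
    idx <- which(chromFactor == ch)
    L <- length(idx)
    block <- z[idx, , drop = FALSE]
    cs <- apply(block, 2, cumsum)
    if (L == 1L) cs <- matrix(cs, nrow = 1L)
    for (i in seq_len(L)) {
      b <- .windowBounds(i, L, as.integer(w))
      lo <- b[1L]; hi <- b[2L]
      tot <- if (lo == 1L) cs[hi, ] else cs[hi, ] - cs[lo - 1L, ]
      smoothed[idx[i], ] <- tot / (hi - lo + 1L)
    }
  }

  prof <- t(smoothed)  # cells x genes
  if (centering == "median") {
    prof <- prof - apply(prof, 1, stats::median)
  } else if (centering == "mean") {
    prof <- prof - rowMeans(prof)
  }
  gi <- DataFrame(gene_id = rownames(z),
                  chromosome = as.character(ann$chromosome),
                  start = ann$start)
  methods::new("CnvProfile", profile = prof, geneInfo = gi,
               windowSize = as.integer(w), centering = centering,
               referenceAdjusted = FALSE)
}

#' Reference-cell adjustment of a CNV profile
#'
#' Subtracts, per gene, the mean smoothed value over the reference
#' (non-epithelial) cells from every cell's profile.
#'
#' @param profile a [CnvProfile].
#' @param referenceCells character vector of reference cell IDs, all present
#'   in the profile.
#' @return adjusted [CnvProfile].
#' @export
referenceAdjust <- function(profile, referenceCells) {
  stopifnot(is(profile, "CnvProfile"))
  if (length(referenceCells) == 0L) stop("empty reference cell set")
  m <- profile@profile
  missing <- setdiff(referenceCells, rownames(m))
  if (length(missing))
    stop("reference cells absent from the profile: ",
         paste(utils::head(missing, 5), collapse = ", "))
  refMean <- colMeans(m[referenceCells, , drop = FALSE])
  profile@profile <- sweep(m, 2, refMean, `-`)
  profile@referenceAdjusted <- TRUE
  profile
}

#' CNV signal strength (mean square)
#'
#' Per-cell mean of the squared smoothed profile values.
#'
#' @param profile a [CnvProfile], or a numeric vector (single profile).
#' @return named numeric vector of MS values (or a scalar for a vector input).
#' @export
computeMs <- function(profile) {
  if (is.numeric(profile) && is.null(dim(profile)))
    return(mean(profile^2))
  stopifnot(is(profile, "CnvProfile"))
  rowMeans(profile@profile^2)
}

#' Correlation with the top-MS mean profile
#'
#' Ranks cells by MS, takes the top `max(1, ceiling(topFraction * n))` cells
#' (ties broken by cell ID), and correlates every cell's profile with the
#' gene-wise mean profile of that top set. Zero-variance profiles get
#' correlation 0 with a warning.
#'
#' @param profile a [CnvProfile] with at least 2 cells.
#' @param topFraction fraction of cells in the top set (default 0.05).
#' @param ms optional precomputed MS vector (named by cell).
#' @return named numeric vector of correlations in `[-1, 1]`.
#' @export
computeCorr <- function(profile, topFraction = 0.05, ms = NULL) {
  stopifnot(is(profile, "CnvProfile"))
  m <- profile@profile
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 cells")
  if (is.null(ms)) ms <- computeMs(profile)
  ms <- ms[rownames(m)]
  nTop <- max(1L, as.integer(ceiling(topFraction * n)))
  topCells <- rownames(m)[order(-ms, rownames(m))][seq_len(nTop)]
  topMean <- colMeans(m[topCells, , drop = FALSE])
  vapply(rownames(m), function(cid) {
    .safeCor(m[cid, ], topMean, warnLabel = cid)
  }, numeric(1))
}

#' Threshold classification of malignancy
#'
#' A cell is malignant iff `MS > msThreshold` or `CORR > corrThreshold`
#' (strict inequalities).
#'
#' @param ms named numeric MS per cell.
#' @param corr named numeric CORR per cell (same cells).
#' @param msThreshold MS cutoff (default 0.02).
#' @param corrThreshold CORR cutoff (default 0.2).
#' @param topFraction recorded top-set fraction (default 0.05).
#' @return a [MalignancyCalls].
#' @export
classifyMalignant <- function(ms, corr, msThreshold = 0.02,
                              corrThreshold = 0.2, topFraction = 0.05) {
  stopifnot(identical(names(ms), names(corr)))
  calls <- DataFrame(
    cell_id = names(ms),
    MS = unname(ms),
    CORR = unname(corr),
    malignant = unname(ms > msThreshold | corr > corrThreshold),
    row.names = names(ms)
  )
  methods::new("MalignancyCalls", calls = calls, msThreshold = msThreshold,
               corrThreshold = corrThreshold, topFraction = topFraction)
}

#' Full CNV malignancy pipeline
#'
#' Composes gene filtering, z-scoring, sliding-window smoothing, per-gene
#' reference adjustment and MS/CORR classification. Epithelial cells (per the
#' `compartment` metadata column) are the query; all other compartments serve
#' as the normal reference. MS and CORR are computed over the query cells on
#' the reference-adjusted profile by default.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with a `lognorm`
#'   assay, a `compartment` column in `colData`, and `chromosome`/`start`
#'   columns in `rowData`.
#' @param w smoothing window width in genes (default 100).
#' @param minCells,minMeanLog2 gene-filter parameters (see [cnvGeneFilter()]).
#' @param msThreshold,corrThreshold,topFraction classification parameters.
#' @param centering per-cell centering of the smoothed profile.
#' @param adjustReference subtract the per-gene reference-cell mean after
#'   smoothing (default TRUE).
#' @param statsOn compute MS/CORR on the `"adjusted"` (default) or
#'   `"unadjusted"` profile.
#' @return list with `calls` (a [MalignancyCalls] over the query cells) and
#'   `profile` (the [CnvProfile] over all cells).
#' @export
runCnvPipeline <- function(sce, w = 100, minCells = 10, minMeanLog2 = 0.1,
                           msThreshold = 0.02, corrThreshold = 0.2,
                           topFraction = 0.05,
                           centering = c("median", "mean", "none"),
                           adjustReference = TRUE,
                           statsOn = c("adjusted", "unadjusted")) {
  centering <- match.arg(centering)
  statsOn <- match.arg(statsOn)
  stopifnot(is(sce, "SummarizedExperiment"))
  cd <- SummarizedExperiment::colData(sce)
  if (!"compartment" %in% colnames(cd))
    stop("colData must contain a 'compartment' column")
  query <- colnames(sce)[cd$compartment == "epithelial"]
  reference <- colnames(sce)[cd$compartment != "epithelial"]
  if (length(query) == 0L) stop("no epithelial query cells")
  if (length(reference) == 0L) stop("no non-epithelial reference cells")

  mat <- .getAssay(sce, "lognorm")
  mat <- cnvGeneFilter(mat, minCells = minCells, minMeanLog2 = minMeanLog2)
  z <- zscoreClamp(mat)
  ann <- SummarizedExperiment::rowData(sce)[rownames(z), , drop = FALSE]
  colnames(ann)[colnames(ann) == "start_position"] <- "start"
  ann$gene_id <- rownames(z)
  profile <- smoothWindows(z, ann, w = w, centering = centering)
  adjusted <- if (adjustReference) referenceAdjust(profile, reference)
              else profile
  statsProfile <- if (statsOn == "adjusted") adjusted else profile

  queryProfile <- statsProfile
  queryProfile@profile <- statsProfile@profile[query, , drop = FALSE]
  ms <- computeMs(queryProfile)
  corr <- computeCorr(queryProfile, topFraction = topFraction, ms = ms)
  calls <- classifyMalignant(ms, corr, msThreshold = msThreshold,
                             corrThreshold = corrThreshold,
                             topFraction = topFraction)
  list(calls = calls, profile = adjusted)
}

#' Write a malignancy call report
#'
#' @param calls a [MalignancyCalls].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeMalignancyCalls <- function(calls, path) {
  stopifnot(is(calls, "MalignancyCalls"))
  utils::write.table(as.data.frame(calls@calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
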