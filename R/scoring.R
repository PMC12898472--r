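#' Binned-control module scores
#'
#' For each signature, the per-cell score is the mean normalized expression of
#' the signature genes minus the mean expression of control genes. Controls
#' are drawn per signature gene (with replacement, under a fixed seed) from
#' the same average-expression bin, where all genes are split into `nBins`
#' near-equal bins by their rank of average expression across cells.
#' Signature genes absent from the matrix are dropped with a warning; a
#' signature with no matched genes is an error.
#'
#' The procedure is invariant to gene row order: bins are formed from
#' tie-averaged ranks and controls are sampled from the bin's sorted gene
#' list.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a `lognorm`
#'   assay, or a genes x cells normalized matrix.
#' @param sets named list of gene-ID vectors.
#' @param nBins number of average-expression bins (default 25).
#' @param nCtrl control genes drawn per signature gene (default 100).
#' @param seed integer seed for the control draws.
#' @param ... passed between methods.
#' @return numeric matrix, cells x signatures.
#' @export
setGeneric("scoreModules", function(x, sets, ...) standardGeneric("scoreModules"))

.scoreModulesMatrix <- function(mat, sets, nBins, nCtrl, seed) {
  mat <- .assertMatrix(mat)
  stopifnot(is.list(sets), !is.null(names(sets)))
  avg <- rowMeans(mat)
  nGenes <- nrow(mat)
  bin <- ceiling(rank(avg, ties.method = "average") * nBins / nGenes)
  bin <- pmin(pmax(bin, 1L), nBins)
  names(bin) <- rownames(mat)
  binGenes <- split(names(bin), bin)
  binGenes <- lapply(binGenes, sort)

  scores <- matrix(NA_real_, ncol(mat), length(sets),
                   dimnames = list(colnames(mat), names(sets)))
  for (si in seq_along(sets)) {
    setName <- names(sets)[si]
    genes <- intersect(sets[[si]], rownames(mat))
    nMissing <- length(setdiff(sets[[si]], rownames(mat)))
    if (length(genes) == 0L)
      stop("signature '", setName, "' shares no genes with the matrix")
    if (nMissing > 0)
      warning("signature '", setName, "': ", nMissing,
              " gene(s) absent from the matrix, dropped")
    genes <- sort(genes)
    ctrl <- .withSeed(.subSeed(seed, si), {
      unlist(lapply(genes, function(g) {
        pool <- binGenes[[as.character(bin[[g]])]]
        pool[sample.int(length(pool), nCtrl, replace = TRUE)]
      }), use.names = FALSE)
    })
    setMean <- colMeans(mat[genes, , drop = FALSE])
    ctrlMean <- colMeans(mat[ctrl, , drop = FALSE])
    scores[, si] <- setMean - ctrlMean
  }
  scores
}

#' @rdname scoreModules
#' @export
setMethod("scoreModules", "matrix",
  function(x, sets, nBins = 25, nCtrl = 100, seed = 1, ...) {
    .scoreModulesMatrix(x, sets, nBins, nCtrl, seed)
  })

#' @rdname scoreModules
#' @export
setMethod("scoreModules", "SingleCellExperiment",
  function(x, sets, nBins = 25, nCtrl = 100, seed = 1, ...) {
    .scoreModulesMatrix(.getAssay(x, "lognorm"), sets, nBins, nCtrl, seed)
  })

#' Assign each cell to its highest-scoring metaprogram
#'
#' Argmax over signature columns; ties are broken by lexicographic signature
#' name order.
#'
#' @param scores cells x signatures score matrix (see [scoreModules()]).
#' @return named character vector, cell to signature label.
#' @export
assignMetaprogram <- function(scores) {
  scores <- .assertMatrix(scores, "score matrix")
  if (ncol(scores) < 1L) stop("need at least one scored signature")
  nm <- colnames(scores)
  lab <- apply(scores, 1, function(s) {
    cand <- nm[s == max(s)]
    sort(cand)[1L]
  })
  stats::setNames(as.character(lab), rownames(scores))
}

#' Classify clusters as patient-specific or patient-shared
#'
#' Per cluster, the maximal single-patient contribution
#' (cells of that patient / cluster size); a cluster is patient-specific when
#' the maximum is at or above `threshold` (inclusive).
#'
#' @param meta cell metadata with `patient_id` and `cluster_label` columns.
#' @param threshold patient-specificity cutoff (default 0.90, inclusive).
#' @return [S4Vectors::DataFrame] with columns `cluster_label`, `n_cells`,
#'   `max_patient`, `max_patient_fraction`, `classification`.
#' @export
classifyClusterSpecificity <- function(meta, threshold = 0.90) {
  meta <- DataFrame(meta)
  need <- c("patient_id", "cluster_label")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  keep <- !is.na(meta$cluster_label)
  if (any(!keep)) warning("excluding ", sum(!keep), " cell(s) without cluster")
  meta <- meta[keep, , drop = FALSE]
  clusters <- sort(unique(as.character(meta$cluster_label)))
  rows <- lapply(clusters, function(cl) {
    sub <- meta[meta$cluster_label == cl, , drop = FALSE]
    tab <- table(as.character(sub$patient_id))
    frac <- as.numeric(tab) / nrow(sub)
    i <- which.max(frac)
    DataFrame(cluster_label = cl, n_cells = nrow(sub),
              max_patient = names(tab)[i], max_patient_fraction = frac[i],
              classification = if (frac[i] >= threshold) "patient_specific"
                               else "patient_shared")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$cluster_label
  out
}

#' Malignant-cell fraction per cluster
#'
#' @param calls a [MalignancyCalls] covering the clustered cells.
#' @param meta cell metadata with `cell_id` and `cluster_label`.
#' @return named numeric vector, cluster to malignant fraction.
#' @export
malignantFractionPerCluster <- function(calls, meta) {
  stopifnot(is(calls, "MalignancyCalls"))
  meta <- DataFrame(meta)
  mal <- isMalignant(calls)
  cells <- intersect(meta$cell_id, names(mal))
  if (length(cells) < length(meta$cell_id))
    stop("malignancy calls do not cover all clustered cells")
  cl <- as.character(meta$cluster_label[match(cells, meta$cell_id)])
  tapply(mal[cells], cl, mean)[sort(unique(cl))]
}
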