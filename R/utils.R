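## Internal helpers shared across the package.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded draws inside the
#' package never perturb user-level random streams.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## derive a stream-specific sub-seed from a master seed; stays < 2^31
.subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

.assertMatrix <- function(x, what = "expression matrix") {
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry row (gene) and column (observation) names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene IDs in ", what)
  if (anyDuplicated(colnames(x)))
    stop("duplicate observation IDs in ", what)
  x
}

.assertCounts <- function(x) {
  x <- .assertMatrix(x, "count matrix")
  if (any(x < 0)) stop("count matrix contains negative values")
  if (any(abs(x - round(x)) > 1e-8)) stop("count matrix is not integral-valued")
  x
}

## Pull a named assay from an SCE/SE or pass a plain matrix through.
.getAssay <- function(x, layer) {
  if (is(x, "SummarizedExperiment")) {
    if (!layer %in% SummarizedExperiment::assayNames(x))
      stop("assay '", layer, "' not present; run the upstream step first")
    return(.assertMatrix(as.matrix(SummarizedExperiment::assay(x, layer)),
                         paste0("'", layer, "' assay")))
  }
  .assertMatrix(x)
}

## row variances without matrixStats
.rowVars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

## Pearson correlation that maps zero-variance input to 0 (with a warning)
.safeCor <- function(x, y, warnLabel = NULL) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    if (!is.null(warnLabel))
      warning("zero-variance profile for ", warnLabel, "; correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}
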