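## Multi-rank NMF on malignant cells and cosine-similarity consensus
## integration into metaprograms.

## Deterministic NNDSVD-style initialization (Boutsidis & Gallopoulos):
## leading SVD pair seeds the first factor; subsequent pairs are split into
## their positive/negative parts and the larger-norm side is kept. Zero
## entries are filled with small seeded uniform values so multiplicative
## updates can move them.
.nndsvdInit <- function(V, k, seed) {
  sv <- svd(V, nu = k, nv = k)
  m <- nrow(V); n <- ncol(V)
  W <- matrix(0, m, k)
  H <- matrix(0, k, n)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        scale <- sqrt(sv$d[j] * nup * nvp)
        if (nup > 0) W[, j] <- scale * up / nup
        if (nvp > 0) H[j, ] <- scale * vp / nvp
      } else {
        scale <- sqrt(sv$d[j] * nun * nvn)
        if (nun > 0) W[, j] <- scale * un / nun
        if (nvn > 0) H[j, ] <- scale * vn / nvn
      }
    }
  }
  eps <- mean(V) * 1e-4
  .withSeed(seed, {
    W[W <= 0] <- stats::runif(sum(W <= 0), 0, eps)
    H[H <= 0] <- stats::runif(sum(H <= 0), 0, eps)
  })
  list(W = W, H = H)
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error `||V - W H||_F` with
#' Lee-Seung multiplicative updates from a deterministic NNDSVD-style
#' initialization. Iteration stops at `maxIter` or when the relative
#' objective decrease falls below `tol`.
#'
#' @param V nonnegative genes x cells matrix.
#' @param k factorization rank.
#' @param seed integer seed (used only to fill zero entries of the
#'   deterministic initialization).
#' @param maxIter maximum iterations (default 500).
#' @param tol relative objective-change tolerance (default 1e-5).
#' @return list with `W` (genes x k), `H` (k x cells) and `objective`
#'   (Frobenius norm of the residual per iteration, non-increasing).
#' @export
nmfFit <- function(V, k, seed = 1, maxIter = 500, tol = 1e-5) {
  V <- .assertMatrix(V, "NMF input")
  if (any(V < 0)) stop("NMF input must be nonnegative")
  if (k < 1 || k > min(dim(V))) stop("invalid rank k")
  init <- .nndsvdInit(V, k, seed)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    err <- sqrt(sum((V - W %*% H)^2))
    obj <- c(obj, err)
    if (is.finite(prev) && prev - err < tol * max(prev, eps)) break
    prev <- err
  }
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  list(W = W, H = H, objective = obj)
}

#' Extract a factor signature by cumulative weight
#'
#' Genes are sorted by descending weight (ties by gene ID); the signature is
#' the smallest prefix whose cumulative weight reaches
#' `weightExplained * total`, capped at `maxLength` genes.
#'
#' @param weights named nonnegative numeric gene weights, not all zero.
#' @param weightExplained cumulative-weight threshold in `(0, 1]`
#'   (default 0.8).
#' @param maxLength signature length cap (default 50).
#' @return character vector of gene IDs, highest weight first.
#' @export
extractSignature <- function(weights, weightExplained = 0.8, maxLength = 50) {
  stopifnot(!is.null(names(weights)), all(weights >= 0))
  tot <- sum(weights)
  if (tot == 0) stop("all-zero factor weights")
  ord <- order(-weights, names(weights))
  w <- weights[ord]
  nonzero <- w > 0
  cum <- cumsum(w) / tot
  nNeed <- which(cum >= weightExplained - 1e-12)[1L]
  n <- min(nNeed, sum(nonzero), maxLength)
  names(w)[seq_len(n)]
}

#' Per-sample multi-rank NMF programs
#'
#' For each sample, restricts the matrix to that sample's (malignant) cells
#' and the sample's top highly variable genes, then factorizes at every rank
#' in `kRange`. One program is emitted per factor; samples with fewer cells
#' than `max(kRange)` are skipped with a warning.
#'
#' @param mats named list of nonnegative genes x cells matrices, one per
#'   sample (normalized expression of the cells to factorize).
#' @param kRange integer vector of ranks (default `4:9`).
#' @param nfeatures highly variable genes per sample (default 1000; capped at
#'   the gene count).
#' @param weightExplained signature cumulative-weight threshold (default 0.8).
#' @param maxSignature signature length cap (default 50).
#' @param center per-gene center the matrix within each sample and truncate
#'   negative residuals at zero before factorizing (default TRUE). Without
#'   centering the leading factors absorb shared baseline expression instead
#'   of cell-state programs.
#' @param seed integer seed.
#' @return an [NmfProgramSet].
#' @export
runNmfMultirank <- function(mats, kRange = 4:9, nfeatures = 1000,
                            weightExplained = 0.8, maxSignature = 50,
                            center = TRUE, seed = 1) {
  stopifnot(is.list(mats), !is.null(names(mats)))
  kRange <- sort(as.integer(kRange))
  programs <- list()
  for (sampleId in names(mats)) {
    V <- .assertMatrix(mats[[sampleId]], paste0("sample ", sampleId))
    if (ncol(V) < max(kRange)) {
      warning("sample ", sampleId, " has fewer cells (", ncol(V),
              ") than max rank; skipped")
      next
    }
    nf <- min(nfeatures, nrow(V))
    hvg <- selectHvg(V, n = nf)
    V <- V[hvg, , drop = FALSE]
    if (center) V <- pmax(V - rowMeans(V), 0)
    keep <- rowSums(V) > 0
    V <- V[keep, , drop = FALSE]
    for (k in kRange) {
      fit <- nmfFit(V, k, seed = .subSeed(seed, k + 1000L * match(sampleId, names(mats))))
      for (f in seq_len(k)) {
        w <- fit$W[, f]
        if (sum(w) == 0) next
        programs[[length(programs) + 1L]] <- list(
          sample_id = sampleId, k = k, factor = f, weights = w,
          signature = extractSignature(w, weightExplained, maxSignature)
        )
      }
    }
  }
  methods::new("NmfProgramSet", programs = programs, kRange = kRange,
               nfeatures = as.integer(nfeatures),
               weightExplained = weightExplained)
}

## cosine similarity between two sparse named weight vectors
.cosine <- function(a, b) {
  genes <- union(names(a), names(b))
  x <- stats::setNames(numeric(length(genes)), genes)
  y <- x
  x[names(a)] <- a
  y[names(b)] <- b
  den <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  if (den == 0) return(0)
  sum(x * y) / den
}

#' Integrate factor programs into consensus metaprograms
#'
#' Computes pairwise cosine similarity between program weight vectors
#' (aligned on the gene union, missing weights zero), clusters programs by
#' average-linkage hierarchical clustering on `1 - cosine`, cuts the tree
#' into `nMp` clusters, and defines each consensus signature as the genes
#' contained in at least `minConfidence` of the member programs' signatures
#' (ordered by decreasing confidence, ties by gene ID).
#'
#' @param programSet an [NmfProgramSet] with at least `nMp` programs.
#' @param nMp number of consensus metaprograms (required; default 8).
#' @param minConfidence membership-fraction threshold in `(0, 1]`
#'   (default 0.3).
#' @return a [MetaprogramSet]; metaprograms are named `MP1..MPn` in
#'   decreasing member count.
#' @export
integratePrograms <- function(programSet, nMp = 8, minConfidence = 0.3) {
  stopifnot(is(programSet, "NmfProgramSet"))
  progs <- programSet@programs
  nProg <- length(progs)
  if (nProg < nMp)
    stop("fewer programs (", nProg, ") than requested metaprograms (", nMp, ")")
  sim <- matrix(1, nProg, nProg)
  for (i in seq_len(nProg - 1L)) {
    for (j in (i + 1L):nProg) {
      s <- .cosine(progs[[i]]$weights, progs[[j]]$weights)
      sim[i, j] <- sim[j, i] <- s
    }
  }
  ids <- vapply(progs, function(p)
    sprintf("%s.k%d.f%d", p$sample_id, p$k, p$factor), "")
  dimnames(sim) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = nMp)

  ## order clusters by decreasing size, then by first member, for stable names
  sizes <- table(cl)
  ordCl <- order(-as.numeric(sizes), as.numeric(names(sizes)))
  clusterIds <- as.numeric(names(sizes))[ordCl]
  signaturesL <- list(); confidenceL <- list(); membersL <- list()
  for (ci in seq_along(clusterIds)) {
    members <- which(cl == clusterIds[ci])
    sigs <- lapply(progs[members], `[[`, "signature")
    genes <- sort(unique(unlist(sigs)))
    conf <- vapply(genes, function(g)
      mean(vapply(sigs, function(s) g %in% s, logical(1))), numeric(1))
    keep <- conf >= minConfidence
    conf <- conf[keep]
    conf <- conf[order(-conf, names(conf))]
    signaturesL[[ci]] <- names(conf)
    confidenceL[[ci]] <- conf
    membersL[[ci]] <- unname(members)
  }
  names(signaturesL) <- names(confidenceL) <- names(membersL) <-
    paste0("MP", seq_along(clusterIds))
  methods::new("MetaprogramSet", signatures = signaturesL,
               confidence = confidenceL, members = membersL,
               programSet = programSet, minConfidence = minConfidence,
               similarity = sim)
}

#' Pairwise Pearson correlation of metaprogram scores
#'
#' Symmetric matrix of Pearson correlations between per-cell metaprogram
#' score columns; zero-variance columns yield 0 off-diagonal entries with a
#' warning; the diagonal is 1.
#'
#' @param scores cells x metaprograms score matrix (>= 3 cells).
#' @return metaprograms x metaprograms correlation matrix.
#' @export
correlateMetaprograms <- function(scores) {
  scores <- .assertMatrix(scores, "score matrix")
  if (nrow(scores) < 3L) stop("need at least 3 scored cells")
  p <- ncol(scores)
  out <- diag(1, p)
  dimnames(out) <- list(colnames(scores), colnames(scores))
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance score column(s): ",
            paste(colnames(scores)[sds == 0], collapse = ", "))
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      r <- if (sds[i] == 0 || sds[j] == 0) 0
           else stats::cor(scores[, i], scores[, j])
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}
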