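## Independent brute-force oracles and tiny fixture builders shared across
## test files. These re-derive the documented definitions directly and never
## call the package's internal helpers.

## named genes x cells matrix with reproducible uniform noise
rndMatrix <- function(nGenes, nCells, seed, min = 0, max = 3) {
  set.seed(seed)
  matrix(runif(nGenes * nCells, min, max), nGenes, nCells,
         dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                         sprintf("c%03d", seq_len(nCells))))
}

## annotation spreading genes over chromosomes in row order
mkAnnotation <- function(geneIds, nChrom = 4) {
  per <- ceiling(length(geneIds) / nChrom)
  data.frame(
    gene_id = geneIds,
    chromosome = rep(paste0("chr", seq_len(nChrom)), each = per)[seq_along(geneIds)],
    start = unlist(lapply(rle(rep(paste0("chr", seq_len(nChrom)),
                                  each = per)[seq_along(geneIds)])$lengths,
                          function(L) seq(0, by = 1000, length.out = L))),
    stringsAsFactors = FALSE
  )
}

## Brute-force sliding-window smoothing: window of up to w genes centered on
## each gene, truncated at chromosome bounds, then per-cell median centering.
## Returns a cells x genes matrix in (chromosome, start, gene_id) order.
bruteSmooth <- function(z, ann, w, centering = "median") {
  ann <- ann[match(rownames(z), ann$gene_id), ]
  ord <- order(ann$chromosome, ann$start, rownames(z))
  z <- z[ord, , drop = FALSE]
  ann <- ann[ord, , drop = FALSE]
  sm <- matrix(NA_real_, nrow(z), ncol(z), dimnames = dimnames(z))
  for (g in seq_len(nrow(z))) {
    sameChrom <- which(ann$chromosome == ann$chromosome[g])
    i <- match(g, sameChrom)
    L <- length(sameChrom)
    lo <- max(1, i - floor((w - 1) / 2))
    hi <- min(L, i + floor(w / 2))
    win <- sameChrom[lo:hi]
    for (cc in seq_len(ncol(z))) sm[g, cc] <- mean(z[win, cc])
  }
  prof <- t(sm)
  if (centering == "median") {
    for (cc in seq_len(nrow(prof))) prof[cc, ] <- prof[cc, ] - median(prof[cc, ])
  } else if (centering == "mean") {
    for (cc in seq_len(nrow(prof))) prof[cc, ] <- prof[cc, ] - mean(prof[cc, ])
  }
  prof
}

## Brute-force CORR: rank cells by mean-square, take ceiling(frac * n) top
## cells (ties by cell ID), correlate each cell with the top-set mean.
bruteCorr <- function(prof, topFraction = 0.05) {
  ms <- apply(prof, 1, function(v) mean(v^2))
  nTop <- max(1, ceiling(topFraction * nrow(prof)))
  top <- rownames(prof)[order(-ms, rownames(prof))][seq_len(nTop)]
  topMean <- apply(prof[top, , drop = FALSE], 2, mean)
  sapply(rownames(prof), function(cid) cor(prof[cid, ], topMean))
}

## Brute-force HVG statistic per its documented definition: polynomial fit of
## log10 variance on log10 mean, clipped standardized values, ranked by the
## variance of those values (ties by gene ID).
bruteHvg <- function(mat, n, degree = 2) {
  mu <- apply(mat, 1, mean)
  v <- apply(mat, 1, var)
  stat <- setNames(rep(0, nrow(mat)), rownames(mat))
  ok <- v > 0 & mu > 0
  fit <- lm(log10(v[ok]) ~ poly(log10(mu[ok]), degree))
  esd <- sqrt(10^fitted(fit))
  zc <- (mat[ok, , drop = FALSE] - mu[ok]) / esd
  zc <- pmin(zc, sqrt(ncol(mat)))
  stat[ok] <- apply(zc, 1, var)
  names(sort(stat, decreasing = TRUE))  # stable ties need explicit order
  rownames(mat)[order(-stat, rownames(mat))][seq_len(n)]
}

## Cox partial likelihood for a single covariate, maximized numerically,
## with a numerically differentiated Wald test (no censoring support needed
## beyond the event indicator).
bruteCoxWald <- function(x, time, event) {
  negLogPL <- function(b) {
    ord <- order(time)
    x <- x[ord]; event <- event[ord]; time <- time[ord]
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -ll
  }
  opt <- optimize(negLogPL, c(-20, 20))
  bhat <- opt$minimum
  h <- 1e-4
  info <- (negLogPL(bhat + h) - 2 * negLogPL(bhat) + negLogPL(bhat - h)) / h^2
  se <- 1 / sqrt(info)
  list(beta = bhat, se = se, p = 2 * pnorm(-abs(bhat / se)))
}

## small single-cell fixture shared by several files
smallScSim <- function(seed = 11, nGenes = 2000, malignantFraction = 0.3) {
  segs <- data.frame(chromosome = c("chr01", "chr03", "chr05"),
                     start = c(10, 5, 15), end = c(70, 65, 75),
                     log2_fold = c(0.5, -0.5, 0.5))
  simulateScrna(nPatients = 3, cellsPerPatient = 60, nGenes = nGenes,
                malignantFraction = malignantFraction, cnvSegments = segs,
                nChromosomes = 10, seed = seed)
}
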