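test_that("CNV gene filter applies both informativeness rules", {
  ## 12 cells; g1 in 9 cells (dropped), g2 low mean (dropped), g3 passes
  m <- matrix(0, 3, 12, dimnames = list(c("g1", "g2", "g3"),
                                        sprintf("c%02d", 1:12)))
  m["g1", 1:9] <- 1
  m["g2", ] <- 0.05 * log(2)   # mean log2 expression = 0.05
  m["g3", ] <- 1
  out <- cnvGeneFilter(m, minCells = 10, minMeanLog2 = 0.1)
  expect_identical(rownames(out), "g3")
  expect_error(cnvGeneFilter(m[1:2, , drop = FALSE]), "no genes survive")

  ## hand filter on a toy 6-gene instance
  m2 <- rndMatrix(6, 15, seed = 2, min = 0, max = 1)
  m2[1, 1:10] <- 0                       # detected in 5 cells only
  m2[2, ] <- m2[2, ] * 0.01              # low mean
  keepHand <- sapply(seq_len(6), function(i)
    sum(m2[i, ] > 0) >= 10 && mean(m2[i, ] / log(2)) >= 0.1)
  expect_identical(rownames(cnvGeneFilter(m2)), rownames(m2)[keepHand])
})

test_that("z-scoring uses sample sd and clamps to [-3, 3]", {
  m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", c("a", "b", "c")))
  expect_equal(unname(zscoreClamp(m)[1, ]), c(-1, 0, 1))

  ## an outlier several sd above the mean is clamped to 3
  m2 <- rbind(g1 = c(rep(0, 20), 10))
  colnames(m2) <- sprintf("c%02d", 1:21)
  expect_gt((10 - mean(m2)) / sd(m2), 3)  # sanity: unclamped z exceeds 3
  expect_equal(max(zscoreClamp(m2)), 3)

  m3 <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m3) <- c("a", "b", "c")
  expect_warning(z <- zscoreClamp(m3), "zero-variance")
  expect_identical(rownames(z), "g1")
})

test_that("window smoothing matches the brute-force oracle and its edge cases", {
  ann <- mkAnnotation(sprintf("g%03d", 1:40), nChrom = 3)
  z <- rndMatrix(40, 5, seed = 7, min = -2, max = 2)

  ## w = 1: smoothing is the identity before centering
  p1 <- smoothWindows(z, ann, w = 1, centering = "none")
  ord <- order(ann$chromosome, ann$start, ann$gene_id)
  expect_equal(cnvMatrix(p1), t(z[ord, ]))

  ## constant z: smoothed and centered values are all zero (up to rounding)
  zc <- matrix(1.3, 40, 5, dimnames = dimnames(z))
  expect_lt(max(abs(cnvMatrix(smoothWindows(zc, ann, w = 7)))), 1e-12)

  ## random instances equal the brute-force window mean + median centering
  for (s in c(1, 2)) {
    zz <- rndMatrix(200, 3, seed = s, min = -2, max = 2)
    aa <- mkAnnotation(rownames(zz), nChrom = 5)
    got <- cnvMatrix(smoothWindows(zz, aa, w = 30))
    expect_equal(got, bruteSmooth(zz, aa, 30), tolerance = 1e-12)
  }

  expect_error(smoothWindows(z, ann[-1, ], w = 5), "unannotated")
})

test_that("reference adjustment subtracts the per-gene reference mean", {
  ann <- mkAnnotation(sprintf("g%03d", 1:20), nChrom = 2)
  z <- rndMatrix(20, 4, seed = 5, min = -1, max = 1)
  prof <- smoothWindows(z, ann, w = 5)
  ## one reference cell: exact subtraction of that profile
  adj1 <- referenceAdjust(prof, "c001")
  expect_equal(cnvMatrix(adj1)["c003", ],
               cnvMatrix(prof)["c003", ] - cnvMatrix(prof)["c001", ])
  ## two references: subtraction of their hand-computed mean
  adj2 <- referenceAdjust(prof, c("c001", "c002"))
  handMean <- (cnvMatrix(prof)["c001", ] + cnvMatrix(prof)["c002", ]) / 2
  expect_equal(cnvMatrix(adj2)["c004", ], cnvMatrix(prof)["c004", ] - handMean)
  expect_error(referenceAdjust(prof, character(0)), "empty reference")
})

test_that("MS is the mean square and is homogeneous of degree 2", {
  expect_equal(computeMs(c(0, 0, 0)), 0)
  expect_equal(computeMs(c(0.1, -0.1)), 0.01)
  v <- rnorm(50)
  expect_equal(computeMs(3 * v), 9 * computeMs(v))
})

test_that("CORR agrees with the brute-force top-set oracle", {
  ann <- mkAnnotation(sprintf("g%03d", 1:60), nChrom = 3)
  z <- rndMatrix(60, 10, seed = 13, min = -2, max = 2)
  prof <- smoothWindows(z, ann, w = 9)
  expect_equal(computeCorr(prof), bruteCorr(cnvMatrix(prof)), tolerance = 1e-12)

  ## the single top cell correlates perfectly with itself
  m <- cnvMatrix(prof)
  m["c001", ] <- m["c001", ] * 50   # force c001 to the top by MS
  prof2 <- prof; prof2@profile <- m
  cc <- computeCorr(prof2, topFraction = 0.05)  # ceil(0.05*10) = 1 top cell
  expect_equal(unname(cc["c001"]), 1)

  ## a profile equal to the negated top-set mean gives -1
  top <- names(sort(-computeMs(prof2)))[1]
  m["c002", ] <- -m[top, ]
  prof3 <- prof2; prof3@profile <- m
  ## c002's large negated profile may itself become top; pin the top set
  ms <- computeMs(prof3)
  if (names(which.max(ms)) == top)
    expect_equal(unname(computeCorr(prof3)["c002"]), -1)
})

test_that("malignancy classification uses strict threshold inequalities", {
  ms <- c(a = 0.021, b = 0.02, c = 0)
  corr <- c(a = 0, b = 0.2, c = 0.25)
  calls <- classifyMalignant(ms, corr)
  lab <- isMalignant(calls)
  expect_true(lab[["a"]])    # MS just above 0.02
  expect_false(lab[["b"]])   # both exactly at the boundary
  expect_true(lab[["c"]])    # CORR above 0.2
})

test_that("scaling a cell's profile up never demotes a malignant call", {
  ann <- mkAnnotation(sprintf("g%03d", 1:60), nChrom = 3)
  z <- rndMatrix(60, 8, seed = 3, min = -2, max = 2)
  prof <- smoothWindows(z, ann, w = 9)
  ms <- computeMs(prof); corr <- computeCorr(prof, ms = ms)
  calls <- isMalignant(classifyMalignant(ms, corr))
  for (cid in names(calls)[calls]) {
    m2 <- cnvMatrix(prof)
    m2[cid, ] <- 2 * m2[cid, ]   # amplify: |values| grow, correlation fixed
    p2 <- prof; p2@profile <- m2
    ms2 <- computeMs(p2)
    expect_gt(ms2[[cid]], ms[[cid]])
    expect_true(ms2[[cid]] > 0.02 || cor(m2[cid, ], cnvMatrix(prof)[cid, ]) == 1)
  }
})

test_that("the CNV pipeline is invariant to input gene and cell order", {
  sim <- smallScSim(seed = 17, nGenes = 800)
  sce <- logNormalize(qcFilter(sim$sce, minGenes = 50))
  base <- runCnvPipeline(sce, w = 30)
  perm <- sce[sample(nrow(sce)), sample(ncol(sce))]
  shuffled <- runCnvPipeline(perm, w = 30)
  b <- as.data.frame(malignancyTable(base$calls))
  s <- as.data.frame(malignancyTable(shuffled$calls))
  s <- s[rownames(b), ]
  expect_equal(b$MS, s$MS, tolerance = 1e-12)
  expect_equal(b$CORR, s$CORR, tolerance = 1e-12)
  expect_identical(b$malignant, s$malignant)
})
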