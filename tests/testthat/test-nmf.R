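test_that("NMF recovers an exact rank-1 factorization", {
  w <- runif(30, 0.1, 2); h <- runif(12, 0.1, 2)
  V <- outer(w, h)
  dimnames(V) <- list(sprintf("g%03d", 1:30), sprintf("c%03d", 1:12))
  fit <- nmfFit(V, k = 1, seed = 1)
  rel <- tail(fit$objective, 1) / sqrt(sum(V^2))
  expect_lte(rel, 1e-6)
})

test_that("NMF objective is non-increasing and factors stay nonnegative", {
  V <- rndMatrix(40, 15, seed = 4, min = 0, max = 2)
  fit <- nmfFit(V, k = 4, seed = 2)
  d <- diff(fit$objective)
  expect_true(all(d <= 1e-8 * fit$objective[-length(fit$objective)]))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  fit2 <- nmfFit(V, k = 4, seed = 2)
  expect_identical(fit$W, fit2$W)
})

test_that("block-diagonal structure is recovered factor by factor", {
  set.seed(6)
  blocks <- lapply(0:2, function(b) sprintf("g%03d", b * 10 + 1:10))
  V <- matrix(0.01, 30, 30, dimnames = list(unlist(blocks),
                                            sprintf("c%03d", 1:30)))
  for (b in 1:3)
    V[blocks[[b]], (b - 1) * 10 + 1:10] <- matrix(runif(100, 1, 2), 10, 10)
  fit <- nmfFit(V, k = 3, seed = 3)
  topGenes <- apply(fit$W, 2, function(w) rownames(V)[order(-w)[1:10]])
  recovered <- apply(topGenes, 2, function(tg)
    max(sapply(blocks, function(b) length(intersect(tg, b)))))
  expect_true(all(recovered == 10))
})

test_that("signature extraction follows the cumulative-weight rule", {
  w <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(extractSignature(w, 0.8), c("a", "b"))
  expect_equal(extractSignature(c(only = 2)), "only")
  w2 <- c(a = 0.4, b = 0.3, c = 0.3, d = 0)
  expect_equal(extractSignature(w2, 1.0), c("a", "b", "c"))
  expect_equal(extractSignature(w, 0.8, maxLength = 1), "a")
  expect_error(extractSignature(c(a = 0, b = 0)), "all-zero")
})

test_that("program integration clusters by cosine similarity", {
  mk <- function(id, w) list(sample_id = id, k = 2L, factor = 1L,
                             weights = w, signature = names(w)[w > 0.1])
  wA <- c(g1 = 1, g2 = 1, g3 = 1, g4 = 0)
  wB <- c(g5 = 1, g6 = 1, g7 = 1)
  ps <- methods::new("NmfProgramSet",
                     programs = list(mk("s1", wA), mk("s2", wA * 2),
                                     mk("s3", wB), mk("s4", wB * 0.5)),
                     kRange = 2L, nfeatures = 10L, weightExplained = 0.8)
  mp <- integratePrograms(ps, nMp = 2, minConfidence = 0.5)
  expect_equal(length(signatures(mp)), 2L)
  sim <- mp@similarity
  expect_equal(sim["s1.k2.f1", "s2.k2.f1"], 1)          # parallel vectors
  expect_equal(sim["s1.k2.f1", "s3.k2.f1"], 0)          # disjoint supports
  sigs <- unname(lapply(signatures(mp), sort))
  expect_setequal(sigs, list(c("g1", "g2", "g3"), c("g5", "g6", "g7")))

  ## order invariance up to relabeling
  ps2 <- ps; ps2@programs <- rev(ps@programs)
  mp2 <- integratePrograms(ps2, nMp = 2, minConfidence = 0.5)
  expect_setequal(unname(lapply(signatures(mp2), sort)), sigs)

  expect_error(integratePrograms(ps, nMp = 10), "fewer programs")
})

test_that("metaprogram score correlations match the Pearson formula", {
  sc <- rndMatrix(20, 3, seed = 8)          # 20 cells x 3 programs
  sc <- t(sc); sc <- t(sc)                  # keep dimnames orientation
  colnames(sc) <- c("MP1", "MP2", "MP3")
  rownames(sc) <- sprintf("cell%02d", 1:20)
  cm <- correlateMetaprograms(sc)
  expect_equal(cm, cor(sc), tolerance = 1e-12)
  expect_equal(unname(diag(cm)), rep(1, 3))

  sc2 <- cbind(sc, MP4 = -sc[, "MP1"])
  cm2 <- correlateMetaprograms(sc2)
  expect_equal(cm2["MP1", "MP4"], -1)

  sc3 <- cbind(sc, flat = rep(1, 20))
  expect_warning(cm3 <- correlateMetaprograms(sc3), "zero-variance")
  expect_equal(unname(cm3["MP1", "flat"]), 0)
})
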