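test_that("module scores are zero on a uniform matrix and shift-invariant", {
  m <- matrix(2, 40, 6, dimnames = list(sprintf("g%03d", 1:40),
                                        sprintf("c%03d", 1:6)))
  sc <- scoreModules(m, list(sig = sprintf("g%03d", 1:5)), nBins = 4,
                     nCtrl = 20, seed = 1)
  expect_true(all(sc == 0))

  ## adding a constant to one cell moves set and control means equally
  m2 <- rndMatrix(40, 6, seed = 2)
  sets <- list(sig = sprintf("g%03d", c(3, 9, 18)))
  base <- scoreModules(m2, sets, nBins = 4, nCtrl = 20, seed = 1)
  m3 <- m2; m3[, "c002"] <- m3[, "c002"] + 5
  shifted <- scoreModules(m3, sets, nBins = 4, nCtrl = 20, seed = 1)
  expect_equal(base, shifted, tolerance = 1e-12)
})

test_that("scores equal the subtraction formula when controls are forced", {
  ## two bins of identical genes: the control mean is deterministic
  lowGenes <- sprintf("lo%02d", 1:5)
  hiGenes <- sprintf("hi%02d", 1:5)
  cells <- sprintf("c%02d", 1:4)
  low <- matrix(rep(c(1, 2, 1, 3), each = 5), 5, 4, byrow = FALSE,
                dimnames = list(lowGenes, cells))
  high <- matrix(rep(c(10, 8, 12, 9), each = 5), 5, 4, byrow = FALSE,
                 dimnames = list(hiGenes, cells))
  m <- rbind(low, high)
  sc <- scoreModules(m, list(sig = c("hi01", "hi02")), nBins = 2,
                     nCtrl = 50, seed = 3)
  ## every control draw has the same expression as the bin, so
  ## score = mean(sig genes) - mean(high bin) = 0 here; and for a low-bin
  ## signature analogously
  expect_equal(unname(sc[, "sig"]), rep(0, 4), tolerance = 1e-12)
  sc2 <- scoreModules(m, list(sig = "lo01"), nBins = 2, nCtrl = 50, seed = 3)
  expect_equal(unname(sc2[, "sig"]), rep(0, 4), tolerance = 1e-12)
})

test_that("module scoring is deterministic and row-order invariant", {
  m <- rndMatrix(60, 8, seed = 5)
  sets <- list(a = sprintf("g%03d", c(1, 7, 30)), b = sprintf("g%03d", 40:44))
  s1 <- scoreModules(m, sets, seed = 9)
  s2 <- scoreModules(m, sets, seed = 9)
  expect_identical(s1, s2)
  s3 <- scoreModules(m[sample(nrow(m)), ], sets, seed = 9)
  expect_equal(s1, s3, tolerance = 1e-12)

  expect_error(scoreModules(m, list(bad = c("nope1", "nope2")), seed = 1),
               "shares no genes")
  expect_warning(scoreModules(m, list(a = c(sets$a, "missing")), seed = 1),
                 "absent")
})

test_that("metaprogram assignment is argmax with lexicographic ties", {
  sc <- rbind(c1 = c(MP1 = 0.5, MP2 = 0.1), c2 = c(0.2, 0.2),
              c3 = c(-1, 0))
  lab <- assignMetaprogram(sc)
  expect_equal(unname(lab), c("MP1", "MP1", "MP2"))
  one <- assignMetaprogram(sc[, "MP1", drop = FALSE])
  expect_true(all(one == "MP1"))
})

test_that("planted program cells score and assign to their program", {
  progs <- data.frame(size = c(25, 25), active_fraction = c(0.3, 0.3),
                      effect_size = c(1, 1))
  sim <- simulateScrna(nPatients = 2, cellsPerPatient = 80, nGenes = 400,
                       malignantFraction = 1, programSpecs = progs,
                       refFraction = 0.1, seed = 31)
  sce <- logNormalize(qcFilter(sim$sce, minGenes = 50))
  sc <- scoreModules(sce, sim$truth$program_genes, seed = 7)
  act <- intersect(sim$truth$program_cells$program_1, rownames(sc))
  inact <- setdiff(rownames(sc), sim$truth$program_cells$program_1)
  wt <- wilcox.test(sc[act, "program_1"], sc[inact, "program_1"],
                    alternative = "greater")
  expect_lt(wt$p.value, 0.01)

  ## argmax is only well-defined for cells active in exactly one program;
  ## cells the generator activated for both programs are excluded
  lab <- assignMetaprogram(sc)
  only1 <- setdiff(act, sim$truth$program_cells$program_2)
  acc <- mean(lab[only1] == "program_1")
  expect_gte(acc, 0.9)
})

test_that("cluster specificity threshold is inclusive at 90%", {
  meta <- data.frame(
    cell_id = sprintf("c%02d", 1:30),
    patient_id = c(rep("A", 10),            # pure cluster
                   rep(c("A", "B"), 5),     # 50/50 cluster
                   c(rep("A", 9), "B")),    # 9/10 cluster
    cluster_label = rep(c("pure", "split", "edge"), each = 10)
  )
  cs <- classifyClusterSpecificity(meta)
  expect_equal(cs["pure", "max_patient_fraction"], 1.0)
  expect_equal(cs["pure", "classification"], "patient_specific")
  expect_equal(cs["split", "max_patient_fraction"], 0.5)
  expect_equal(cs["split", "classification"], "patient_shared")
  expect_equal(cs["edge", "max_patient_fraction"], 0.9)
  expect_equal(cs["edge", "classification"], "patient_specific")
})

test_that("malignant fraction per cluster is a plain proportion", {
  cells <- sprintf("c%02d", 1:24)
  ms <- setNames(c(rep(0.5, 12), rep(0, 12)), cells)   # first 12 malignant
  ms[13:15] <- 0.5                                     # 3 of the second 12
  calls <- classifyMalignant(ms, setNames(rep(0, 24), cells))
  meta <- data.frame(cell_id = cells,
                     cluster_label = rep(c("all", "some"), each = 12))
  fr <- malignantFractionPerCluster(calls, meta)
  expect_equal(unname(fr["all"]), 1.0)
  expect_equal(unname(fr["some"]), 0.25)

  none <- classifyMalignant(setNames(rep(0, 24), cells),
                            setNames(rep(0, 24), cells))
  expect_true(all(malignantFractionPerCluster(none, meta) == 0))
})
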