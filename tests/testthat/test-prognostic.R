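test_that("DE between exchangeable groups is null; strong shifts are caught", {
  set.seed(12)
  base <- matrix(rpois(40 * 12, 5), 40, 12,
                 dimnames = list(sprintf("g%03d", 1:40), sprintf("c%02d", 1:12)))
  m <- log1p(base)
  de <- deTest(m, sprintf("c%02d", 1:6), sprintf("c%02d", 7:12))
  expect_true(all(de$p_adj >= de$p - 1e-15))

  ## identical expression in both groups: duplicate the columns
  m2 <- cbind(m[, 1:6], m[, 1:6])
  colnames(m2) <- sprintf("c%02d", 1:12)
  de2 <- deTest(m2, sprintf("c%02d", 1:6), sprintf("c%02d", 7:12))
  expect_true(all(de2$log2FC == 0))
  expect_true(all(de2$p >= 0.9))

  ## a gene at 10 in group A and 0 in group B
  m3 <- m
  m3["g001", 1:6] <- 10; m3["g001", 7:12] <- 0
  de3 <- deTest(m3, sprintf("c%02d", 1:6), sprintf("c%02d", 7:12))
  expect_gt(abs(de3["g001", "log2FC"]), 1)
  expect_equal(de3["g001", "p"], min(de3$p))
})

test_that("BH adjustment reproduces the step-up definition exactly", {
  set.seed(3)
  m <- matrix(rpois(30 * 10, 4) + runif(300), 30, 10,
              dimnames = list(sprintf("g%03d", 1:30), sprintf("c%02d", 1:10)))
  de <- deTest(m, sprintf("c%02d", 1:5), sprintf("c%02d", 6:10))
  n <- nrow(de)
  ord <- order(de$p, decreasing = TRUE)
  stepUp <- de$p[ord] * n / (n:1)
  stepUp <- cummin(pmin(stepUp, 1))[order(ord)]
  expect_equal(de$p_adj, stepUp, tolerance = 1e-15)
  ## the printed worked example of the step-up rule
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("candidate intersection applies both thresholds in both tables", {
  mkDe <- function(genes, lfc, padj) {
    S4Vectors::DataFrame(gene_id = genes, log2FC = lfc, p = padj, p_adj = padj,
                         row.names = genes)
  }
  deA <- mkDe(c("g1", "g2", "g3", "g4"), c(2, 2, 0.5, -2),
              c(0.01, 0.01, 0.01, 0.01))
  deB <- mkDe(c("g2", "g3", "g4", "g5"), c(-3, 2, 2, 2),
              c(0.01, 0.2, 0.01, 0.01))
  ## g2: passes both; g3 fails lfc in A and p in B; g4 passes both
  expect_equal(intersectCandidates(deA, deB), c("g2", "g4"))
  expect_equal(intersectCandidates(deA, mkDe("g9", 3, 0.001)), character(0))
  expect_length(intersectCandidates(deA, deA), 3L)
})

test_that("univariate Cox screen has near-nominal size and high power", {
  nullSim <- simulateBulkSurvival(nSamples = 300, nGenes = 200, seed = 44)
  keep <- univariateCoxScreen(nullSim$expr, nullSim$cohort$time_months,
                              nullSim$cohort$event)
  expect_lt(nrow(keep) / 200, 0.11)   # nominal 5% within binomial slack

  hits <- vapply(1:5, function(s) {
    sim <- simulateBulkSurvival(nSamples = 300, nGenes = 30,
                                causalBetas = c(bg00001 = 1), seed = 200 + s)
    scr <- univariateCoxScreen(sim$expr, sim$cohort$time_months,
                               sim$cohort$event)
    "bg00001" %in% scr$gene_id && scr["bg00001", "HR"] > 1
  }, logical(1))
  expect_true(all(hits))
})

test_that("Cox Wald test matches a brute-force partial-likelihood oracle", {
  set.seed(21)
  n <- 24
  x <- rep(c(0, 1), n / 2)
  time <- sort(rexp(n, 0.1)) + seq(0, 0.001, length.out = n)  # distinct times
  time <- sample(time)
  event <- rep(1L, n)
  oracle <- bruteCoxWald(x, time, event)
  fit <- survival::coxph(survival::Surv(time, event) ~ x)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-4)
  expect_equal(summary(fit)$coefficients[1, "Pr(>|z|)"], oracle$p,
               tolerance = 1e-3)
})

test_that("LASSO keeps a strongly prognostic gene among nulls", {
  sim <- simulateBulkSurvival(nSamples = 400, nGenes = 51,
                              causalBetas = c(bg00001 = 1.2), seed = 77)
  sel <- lassoCoxSelect(sim$expr, sim$cohort$time_months, sim$cohort$event,
                        genes = rownames(sim$expr), seed = 5)
  expect_true("bg00001" %in% sel$genes)
  expect_gt(sel$lambda, 0)
})

test_that("risk model: median split, tie rule and permutation invariance", {
  sim <- simulateBulkSurvival(nSamples = 101, nGenes = 10,
                              causalBetas = c(bg00001 = 1), seed = 15)
  model <- fitRiskModel(sim$expr, sim$cohort$time_months, sim$cohort$event,
                        genes = c("bg00001", "bg00002"))
  sc <- riskScores(model)
  expect_equal(sum(sc > median(sc)), sum(riskGroups(model) == "high"))
  ## the sample sitting exactly at the median goes to the low-risk group
  atMedian <- names(sc)[which.min(abs(sc - median(sc)))]
  expect_equal(as.character(riskGroups(model)[match(atMedian, names(sc))]),
               "low")
  expect_lte(abs(sum(riskGroups(model) == "high") -
                 sum(riskGroups(model) == "low")), 1)

  perm <- sample(ncol(sim$expr))
  model2 <- fitRiskModel(sim$expr[, perm], sim$cohort$time_months[perm],
                         sim$cohort$event[perm],
                         genes = c("bg00001", "bg00002"))
  expect_equal(riskScores(model2)[names(sc)], sc, tolerance = 1e-9)
  expect_identical(as.character(riskGroups(model2)[match(names(sc),
                                                         names(riskScores(model2)))]),
                   as.character(riskGroups(model)))

  ## duplicated gene column makes the design singular
  expr2 <- rbind(sim$expr, dup = sim$expr["bg00001", ])
  expect_error(fitRiskModel(expr2, sim$cohort$time_months, sim$cohort$event,
                            genes = c("bg00001", "dup")), "singular")
})

test_that("model evaluation wires log-rank, AUC and hazard ratios together", {
  betas <- setNames(rep(1, 3), sprintf("bg%05d", 1:3))
  sim <- simulateBulkSurvival(nSamples = 250, nGenes = 20, causalBetas = betas,
                              baselineHazard = 0.01, seed = 33)
  model <- fitRiskModel(sim$expr, sim$cohort$time_months, sim$cohort$event,
                        genes = names(betas))
  ev <- evaluateModel(model, sim$cohort$time_months, sim$cohort$event,
                      covariates = data.frame(age = rnorm(250)))
  expect_lt(logrankTest(ev)$p, 1e-4)
  expect_true(all(timeAuc(ev) > 0.5, na.rm = TRUE))
  hr <- hazardRatios(ev)
  expect_equal(nrow(hr), 2L)
  expect_true(all(hr$HR > 1))
  expect_true(all(hr$lower <= hr$HR & hr$HR <= hr$upper))
})

test_that("signature survival scoring separates a planted causal signature", {
  betas <- setNames(rep(1, 5), sprintf("bg%05d", 1:5))
  sim <- simulateBulkSurvival(nSamples = 300, nGenes = 50, causalBetas = betas,
                              seed = 51)
  res <- scoreSignatureSurvival(sim$expr, sim$cohort$time_months,
                                sim$cohort$event, names(betas))
  expect_lt(res$logrank$p, 0.01)
  expect_error(scoreSignatureSurvival(sim$expr[, 1, drop = FALSE],
                                      sim$cohort$time_months[1],
                                      sim$cohort$event[1], names(betas)),
               "at least 2")
  expect_error(scoreSignatureSurvival(sim$expr, sim$cohort$time_months,
                                      sim$cohort$event, "absent"),
               "no signature genes")
})
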