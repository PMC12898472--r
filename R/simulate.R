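#' Simulate a single-cell cohort with planted CNV segments and programs
#'
#' Generates negative-binomial counts for several patients. Each patient
#' contributes epithelial cells (a configurable fraction of them malignant)
#' plus non-epithelial reference cells (immune/stromal) that carry no CNV.
#' Malignant cells have the negative-binomial means of genes inside planted
#' contiguous chromosome segments multiplied by `2^log2_fold`; cells active
#' for a planted co-expression program have the program genes' means
#' multiplied by `1 + effect_size`. All draws are deterministic for a fixed
#' seed.
#'
#' @param nPatients number of patients (default 5).
#' @param cellsPerPatient epithelial cells per patient (default 100).
#' @param nGenes total genes (default 2000).
#' @param malignantFraction fraction of each patient's epithelial cells that
#'   are malignant, in `[0, 1]`.
#' @param cnvSegments data.frame with columns `chromosome`, `start`, `end`
#'   (1-based gene indices within the chromosome, inclusive) and `log2_fold`
#'   in `[-1, 1]`; segments must not overlap within a chromosome.
#' @param programSpecs data.frame with columns `size` (genes per program),
#'   `active_fraction` (fraction of malignant -- or, if none, epithelial --
#'   cells active) and `effect_size` (> 0).
#' @param nbDispersion negative-binomial size parameter (default 2; variance
#'   `mu + mu^2 / size`).
#' @param refFraction non-epithelial reference cells added per patient, as a
#'   fraction of `cellsPerPatient` (default 0.3).
#' @param nChromosomes chromosomes the genes are spread over (default 22).
#' @param baseMeanLog `c(meanlog, sdlog)` of the log-normal gene base means.
#' @param seed integer seed.
#' @return list with elements `sce` (a
#'   [SingleCellExperiment::SingleCellExperiment] with `counts`, cell metadata
#'   in `colData`, gene annotation in `rowData`) and `truth` (list:
#'   `malignant_cells`, `program_cells`, `program_genes`, `segment_genes`,
#'   `reference_cells`).
#' @export
simulateScrna <- function(nPatients = 5, cellsPerPatient = 100, nGenes = 2000,
                          malignantFraction = 0.3,
                          cnvSegments = NULL, programSpecs = NULL,
                          nbDispersion = 2, refFraction = 0.3,
                          nChromosomes = 22,
                          baseMeanLog = c(meanlog = 0.3, sdlog = 0.8),
                          seed = 1) {
  stopifnot(malignantFraction >= 0, malignantFraction <= 1,
            refFraction >= 0, nbDispersion > 0)
  genesPerChrom <- ceiling(nGenes / nChromosomes)
  chrom <- rep(paste0("chr", sprintf("%02d", seq_len(nChromosomes))),
               each = genesPerChrom)[seq_len(nGenes)]
  withinIdx <- stats::ave(seq_len(nGenes), chrom, FUN = seq_along)
  ann <- DataFrame(
    gene_id = sprintf("g%05d", seq_len(nGenes)),
    chromosome = chrom,
    start = as.integer((withinIdx - 1L) * 1e5L)
  )
  rownames(ann) <- ann$gene_id

  segGenes <- character(0)
  segTable <- list()
  if (!is.null(cnvSegments) && nrow(cnvSegments) > 0) {
    stopifnot(all(c("chromosome", "start", "end", "log2_fold") %in%
                  colnames(cnvSegments)))
    if (any(abs(cnvSegments$log2_fold) > 1))
      stop("log2_fold must lie in [-1, 1]")
    for (ch in unique(cnvSegments$chromosome)) {
      sub <- cnvSegments[cnvSegments$chromosome == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
        stop("overlapping CNV segments on ", ch)
      if (any(sub$end > sum(chrom == ch)))
        stop("CNV segment exceeds the gene span of ", ch)
    }
    for (i in seq_len(nrow(cnvSegments))) {
      s <- cnvSegments[i, ]
      idx <- which(ann$chromosome == s$chromosome &
                   withinIdx >= s$start & withinIdx <= s$end)
      segTable[[i]] <- list(genes = ann$gene_id[idx],
                            log2_fold = s$log2_fold)
    }
    segGenes <- unique(unlist(lapply(segTable, `[[`, "genes")))
  }

  .withSeed(seed, {
    baseMu <- exp(stats::rnorm(nGenes, baseMeanLog[["meanlog"]],
                               baseMeanLog[["sdlog"]]))
    names(baseMu) <- ann$gene_id

    ## cell bookkeeping
    nMalig <- round(malignantFraction * cellsPerPatient)
    nRef <- round(refFraction * cellsPerPatient)
    cellRows <- list()
    for (p in seq_len(nPatients)) {
      pid <- sprintf("P%02d", p)
      epi <- sprintf("%s_epi_%03d", pid, seq_len(cellsPerPatient))
      malig <- utils::head(epi, nMalig)
      ref <- if (nRef > 0) sprintf("%s_ref_%03d", pid, seq_len(nRef))
             else character(0)
      cellRows[[p]] <- data.frame(
        cell_id = c(epi, ref),
        patient_id = pid,
        compartment = c(rep("epithelial", cellsPerPatient),
                        rep(c("immune", "stromal"), length.out = nRef)),
        cluster_label = c(
          ifelse(epi %in% malig, paste0("malig_", pid),
                 paste0("epi_shared_", 1 + (seq_len(cellsPerPatient) %% 2))),
          rep("reference", nRef)),
        tissue = "tumor",
        malignant_truth = c(epi %in% malig, rep(FALSE, nRef)),
        stringsAsFactors = FALSE
      )
    }
    meta <- do.call(rbind, cellRows)
    rownames(meta) <- meta$cell_id
    nCells <- nrow(meta)

    ## program gene sets: drawn from genes outside CNV segments, disjoint
    progGenes <- list()
    progCells <- list()
    if (!is.null(programSpecs) && nrow(programSpecs) > 0) {
      stopifnot(all(c("size", "active_fraction", "effect_size") %in%
                    colnames(programSpecs)))
      pool <- setdiff(ann$gene_id, segGenes)
      eligible <- meta$cell_id[meta$malignant_truth]
      if (length(eligible) == 0L)
        eligible <- meta$cell_id[meta$compartment == "epithelial"]
      for (i in seq_len(nrow(programSpecs))) {
        sz <- programSpecs$size[i]
        if (sz > length(pool)) stop("program gene pool exhausted")
        g <- sort(sample(pool, sz))
        pool <- setdiff(pool, g)
        nActive <- round(programSpecs$active_fraction[i] * length(eligible))
        progGenes[[i]] <- g
        progCells[[i]] <- sort(sample(eligible, nActive))
      }
      names(progGenes) <- names(progCells) <-
        sprintf("program_%d", seq_len(nrow(programSpecs)))
    }

    ## per-cell mean matrix, then one NB draw
    counts <- matrix(0L, nGenes, nCells,
                     dimnames = list(ann$gene_id, meta$cell_id))
    cellFactor <- stats::runif(nCells, 0.8, 1.2)
    for (j in seq_len(nCells)) {
      mu <- baseMu * cellFactor[j]
      if (meta$malignant_truth[j] && length(segTable)) {
        for (s in segTable)
          mu[s$genes] <- mu[s$genes] * 2^s$log2_fold
      }
      if (length(progCells)) {
        for (i in seq_along(progCells)) {
          if (meta$cell_id[j] %in% progCells[[i]])
            mu[progGenes[[i]]] <- mu[progGenes[[i]]] *
              (1 + programSpecs$effect_size[i])
        }
      }
      counts[, j] <- stats::rnbinom(nGenes, size = nbDispersion, mu = mu)
    }

    sce <- makeSce(counts, meta = meta, annotation = ann)
    truth <- list(
      malignant_cells = meta$cell_id[meta$malignant_truth],
      reference_cells = meta$cell_id[meta$compartment != "epithelial"],
      program_cells = progCells,
      program_genes = progGenes,
      segment_genes = lapply(segTable, `[[`, "genes"),
      seed = seed
    )
    list(sce = sce, truth = truth)
  })
}

#' Simulate a bulk expression cohort with log-linear survival
#'
#' Expression values are log-normal per gene; event times are exponential
#' with hazard `baselineHazard * exp(sum(beta_i * z_i))` where `z` is the
#' per-gene standardized expression; censoring times are independent
#' `Uniform(0, tau)` with `tau` solved numerically so that the expected
#' censoring fraction matches `censorRate`.
#'
#' @param nSamples cohort size (default 300).
#' @param nGenes genes simulated (default 200).
#' @param causalBetas named numeric vector: log-hazard coefficient per causal
#'   gene (names must be among the simulated genes `bg00001`, ...); may be
#'   empty for a null cohort.
#' @param baselineHazard exponential baseline hazard per month (default 0.02).
#' @param censorRate target censoring fraction in `[0, 1)` (default 0.3).
#' @param seed integer seed.
#' @return list with `expr` (genes x samples matrix), `cohort`
#'   ([S4Vectors::DataFrame]: `sample_id`, `time_months`, `event`) and `truth`
#'   (list: `causal_betas`, `linear_predictor`).
#' @export
simulateBulkSurvival <- function(nSamples = 300, nGenes = 200,
                                 causalBetas = numeric(0),
                                 baselineHazard = 0.02, censorRate = 0.3,
                                 seed = 1) {
  stopifnot(censorRate >= 0, censorRate < 1, baselineHazard > 0)
  geneIds <- sprintf("bg%05d", seq_len(nGenes))
  if (length(causalBetas) && !all(names(causalBetas) %in% geneIds))
    stop("causal genes must be among the simulated gene IDs")
  .withSeed(seed, {
    meanlog <- stats::rnorm(nGenes, 3, 0.5)
    expr <- matrix(
      exp(stats::rnorm(nGenes * nSamples, meanlog, 0.3)),
      nGenes, nSamples,
      dimnames = list(geneIds, sprintf("S%04d", seq_len(nSamples)))
    )
    z <- t(scale(t(expr)))
    lp <- rep(0, nSamples)
    if (length(causalBetas))
      lp <- drop(crossprod(z[names(causalBetas), , drop = FALSE], causalBetas))
    rate <- baselineHazard * exp(lp)
    eventTime <- stats::rexp(nSamples, rate)
    if (censorRate > 0) {
      censFrac <- function(tau)
        mean((1 - exp(-rate * tau)) / (rate * tau)) - censorRate
      tau <- stats::uniroot(censFrac, lower = 1e-6, upper = 1e8,
                            extendInt = "downX")$root
      censTime <- stats::runif(nSamples, 0, tau)
      time <- pmin(eventTime, censTime)
      event <- as.integer(eventTime <= censTime)
    } else {
      time <- eventTime
      event <- rep(1L, nSamples)
    }
    time <- pmax(time, 1e-6)
    cohort <- DataFrame(
      sample_id = colnames(expr),
      time_months = time,
      event = event,
      row.names = colnames(expr)
    )
    list(expr = expr, cohort = cohort,
         truth = list(causal_betas = causalBetas, linear_predictor = lp))
  })
}

#' Simulate a sample-by-drug AUC table tied to a risk score
#'
#' Sensitive drugs get `AUC = baseline - effect * z(risk) + noise`; all others
#' `AUC = baseline + noise`. AUC values are clipped at zero.
#'
#' @param riskScores named numeric vector of per-sample risk scores.
#' @param nDrugs number of drugs (default 20).
#' @param nSensitive number of planted sensitive drugs (default 3).
#' @param effect effect size on the standardized risk score (default 2).
#' @param noiseSd Gaussian noise standard deviation (default 0.1).
#' @param baselineAuc mean AUC of insensitive drugs (default 10).
#' @param seed integer seed.
#' @return list with `auc` (samples x drugs matrix) and `truth` (list:
#'   `sensitive_drugs`).
#' @export
simulateDrugResponse <- function(riskScores, nDrugs = 20, nSensitive = 3,
                                 effect = 2, noiseSd = 0.1, baselineAuc = 10,
                                 seed = 1) {
  stopifnot(nSensitive <= nDrugs, !is.null(names(riskScores)))
  n <- length(riskScores)
  drugIds <- sprintf("drug_%02d", seq_len(nDrugs))
  .withSeed(seed, {
    sensitive <- sort(sample(drugIds, nSensitive))
    z <- as.numeric(scale(riskScores))
    auc <- matrix(stats::rnorm(n * nDrugs, baselineAuc, noiseSd), n, nDrugs,
                  dimnames = list(names(riskScores), drugIds))
    for (d in sensitive) auc[, d] <- auc[, d] - effect * z
    auc[auc < 0] <- 0
    list(auc = auc, truth = list(sensitive_drugs = sensitive))
  })
}
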