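# tumorImmuneRisk

Risk stratification for triple-negative breast cancer (TNBC) — and any
tumor system with comparable data — built from the interaction between
tumor-cell expression states and the immune microenvironment. The package
implements, as tested R functions over Bioconductor containers, the full
chain from single-cell expression matrices to drug-repurposing candidates:

1. **Malignant-cell calling from inferred CNV** — genes are filtered,
   z-scored (clamped to ±3), sorted by chromosome position and smoothed
   with a 100-gene sliding window; profiles are median-centered per cell
   and adjusted against non-epithelial reference cells. Each cell gets a
   CNV signal strength *MS* (mean square of the profile) and a correlation
   *CORR* with the mean profile of the top-5% highest-MS cells; a cell is
   malignant iff `MS > 0.02` or `CORR > 0.2`.
2. **Heterogeneity classification** — epithelial subclusters are
   patient-specific when one patient contributes ≥ 90% of their cells;
   malignant fractions are reported per cluster.
3. **Metaprograms** — per-sample multi-rank NMF (`k = 4..9`, 1,000
   variable genes, multiplicative updates from NNDSVD initialization) on
   malignant cells; factors are integrated into `nMP` consensus
   metaprograms by average-linkage clustering on cosine similarity, with
   signatures defined by a cumulative-weight rule (80%) and a gene
   confidence threshold (0.3). Cells are scored with binned-control
   module scores (signature mean minus expression-bin-matched control
   mean) and assigned to their argmax metaprogram.
4. **Dual prognostic models** — candidates from the intersection of two
   differential-expression contrasts (BH `p_adj < 0.05`, `|log2FC| > 1`)
   are screened by univariate Cox (`p < 0.05`), selected by LASSO-Cox at
   minimum cross-validated deviance, and combined into a risk score
   `sum(beta_i * z_i)` by multivariate Cox. Patients above the median
   score are high-risk; models are evaluated by Kaplan–Meier/log-rank,
   hazard ratios (raw and covariate-adjusted) and IPCW time-dependent AUC
   at 2/4/6/8 years. The published SPSM panel (10 genes) and the 5 genes
   it shares with the IPSM panel ship as a GMT (`riskSignatures()`).
5. **Drug screen** — over a samples-by-drugs AUC table, drugs pass when
   the AUC log2 fold change (low/high risk) is positive *and* the mean
   correlation between risk-gene expression and AUC is below −0.05.

Synthetic generators with planted ground truth (`simulateScrna()`,
`simulateBulkSurvival()`, `simulateDrugResponse()`) make every stage
testable without external cohorts.

## Worked example

Plant three 200-gene CNV segments (|log2 fold| = 0.5) in 30% of the
epithelial cells of a 6,000-gene cohort, then recover them:

```r
library(tumorImmuneRisk)

segs <- data.frame(chromosome = c("chr01", "chr05", "chr09"),
                   start = c(30, 20, 40), end = c(229, 219, 239),
                   log2_fold = c(0.5, -0.5, 0.5))
sim <- simulateScrna(nPatients = 3, cellsPerPatient = 110, nGenes = 6000,
                     malignantFraction = 0.3, cnvSegments = segs, seed = 1)
sce <- logNormalize(qcFilter(sim$sce))
cnv <- runCnvPipeline(sce)
cnv$calls
#> MalignancyCalls: 330 cells; 114 malignant ( 34.5% )
#>    thresholds: MS > 0.02 | CORR > 0.2 ; top fraction 0.05

mal <- isMalignant(cnv$calls)
mean(mal[intersect(names(mal), sim$truth$malignant_cells)])   # sensitivity
#> [1] 1
mean(!mal[setdiff(names(mal), sim$truth$malignant_cells)])    # specificity
#> [1] 0.935
```

The calls table reports, per epithelial cell, its CNV signal strength
(MS), its correlation with the top-MS mean profile (CORR) and the
resulting label; here every planted malignant cell is recovered and 93.5%
of normal epithelial cells are correctly left uncalled.

Build and evaluate a risk model on a survival cohort with 10 planted
hazardous genes:

```r
set.seed(8)
betas <- setNames(runif(10, 0.5, 1), sprintf("bg%05d", 1:10))
cohort <- simulateBulkSurvival(nSamples = 300, nGenes = 200,
                               causalBetas = betas, seed = 2)
fit <- runPrognosticPipeline(cohort$expr, cohort$cohort$time_months,
                             cohort$cohort$event,
                             candidates = rownames(cohort$expr), seed = 3)
fit$model
#> RiskModel: 13 genes; lambda = 0.01279
#>   cutoff (median score): -0.04824 ; 150 high / 150 low risk samples
fit$eval
#> SurvivalEval: log-rank p =3.11e-64
#>   AUC(24/48/72/96 mo): 0.968, 0.957, 0.958, 0.953
sum(names(betas) %in% riskGenes(fit$model))
#> [1] 10
```

All 10 causal genes sit in the selected panel; the high/low split
separates survival decisively, and the score discriminates 2- to 8-year
outcomes with AUC ≈ 0.95. `screenDrugs()` then takes these risk groups
and genes to a drug AUC table; see the methods vignette
(`vignettes/tumor-immune-risk-methods.Rmd`) for the model details and all
tunable parameters.

A thin command-line wrapper over the same functions is included at
`inst/scripts/riskflow-cli.R` with subcommands `simulate`, `preprocess`,
`cnv-call`, `score`, `metaprograms`, `prognostic` and `drug-screen`.

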