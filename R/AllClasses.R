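#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Smoothed per-cell copy-number profiles
#'
#' Cells-by-genes matrix of sliding-window smoothed, per-cell centered (and
#' optionally reference-adjusted) z-scored expression, used as a proxy for
#' copy-number state. Genes are ordered by (chromosome, start).
#'
#' @slot profile numeric matrix, cells x genes (chromosome-sorted columns).
#' @slot geneInfo [S4Vectors::DataFrame] with columns `gene_id`, `chromosome`,
#'   `start`, one row per profile column, in column order.
#' @slot windowSize integer, number of genes per smoothing window.
#' @slot centering character, per-cell centering applied (`median`, `mean`,
#'   `none`).
#' @slot referenceAdjusted logical, whether the per-gene reference-cell mean
#'   has been subtracted.
#' @exportClass CnvProfile
setClass("CnvProfile",
  slots = c(
    profile = "matrix",
    geneInfo = "DataFrame",
    windowSize = "integer",
    centering = "character",
    referenceAdjusted = "logical"
  )
)

setValidity("CnvProfile", function(object) {
  msg <- NULL
  if (ncol(object@profile) != nrow(object@geneInfo))
    msg <- c(msg, "profile columns and geneInfo rows differ")
  if (!all(is.finite(object@profile)))
    msg <- c(msg, "profile contains non-finite values")
  gi <- object@geneInfo
  if (nrow(gi) > 1L) {
    o <- order(as.character(gi$chromosome), gi$start)
    if (!identical(o, seq_len(nrow(gi))))
      msg <- c(msg, "geneInfo is not sorted by (chromosome, start)")
  }
  if (length(object@windowSize) != 1L || object@windowSize < 1L)
    msg <- c(msg, "windowSize must be a single positive integer")
  if (is.null(msg)) TRUE else msg
})

#' Per-cell malignancy calls
#'
#' Stores the per-cell CNV signal strength (MS, mean square of the smoothed
#' profile), the correlation with the mean profile of the top-MS cell set
#' (CORR), and the resulting malignant/non-malignant label.
#'
#' @slot calls [S4Vectors::DataFrame] with columns `cell_id`, `MS`, `CORR`,
#'   `malignant`.
#' @slot msThreshold numeric, MS cutoff (strict `>`).
#' @slot corrThreshold numeric, CORR cutoff (strict `>`).
#' @slot topFraction numeric, fraction of highest-MS cells defining the
#'   reference mean profile for CORR.
#' @exportClass MalignancyCalls
setClass("MalignancyCalls",
  slots = c(
    calls = "DataFrame",
    msThreshold = "numeric",
    corrThreshold = "numeric",
    topFraction = "numeric"
  )
)

setValidity("MalignancyCalls", function(object) {
  msg <- NULL
  need <- c("cell_id", "MS", "CORR", "malignant")
  if (!all(need %in% colnames(object@calls)))
    msg <- c(msg, paste("calls must have columns", paste(need, collapse = ", ")))
  else {
    cl <- object@calls
    if (any(cl$MS < 0)) msg <- c(msg, "MS must be nonnegative")
    if (any(cl$CORR < -1 - 1e-12 | cl$CORR > 1 + 1e-12))
      msg <- c(msg, "CORR must lie in [-1, 1]")
    expected <- cl$MS > object@msThreshold | cl$CORR > object@corrThreshold
    if (!identical(as.logical(cl$malignant), as.logical(expected)))
      msg <- c(msg, "malignant label inconsistent with MS/CORR thresholds")
    if (anyDuplicated(cl$cell_id)) msg <- c(msg, "duplicate cell_id")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-sample NMF factor programs
#'
#' One entry per (sample, rank, factor): the nonnegative gene-weight vector of
#' the factor and the signature extracted from it by the cumulative-weight
#' rule.
#'
#' @slot programs list; each element a list with fields `sample_id`, `k`,
#'   `factor`, `weights` (named nonnegative numeric), `signature` (character).
#' @slot kRange integer vector of factorization ranks used.
#' @slot nfeatures integer, number of highly variable genes per sample.
#' @slot weightExplained numeric, cumulative-weight threshold used for
#'   signature extraction.
#' @exportClass NmfProgramSet
setClass("NmfProgramSet",
  slots = c(
    programs = "list",
    kRange = "integer",
    nfeatures = "integer",
    weightExplained = "numeric"
  )
)

setValidity("NmfProgramSet", function(object) {
  msg <- NULL
  for (p in object@programs) {
    if (!all(c("sample_id", "k", "factor", "weights", "signature") %in% names(p))) {
      msg <- c(msg, "each program needs sample_id, k, factor, weights, signature")
      break
    }
    if (any(p$weights < 0)) { msg <- c(msg, "negative factor weights"); break }
    if (!all(p$signature %in% names(p$weights))) {
      msg <- c(msg, "signature genes must be weighted genes"); break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Consensus metaprograms
#'
#' Consensus gene programs obtained by clustering per-sample NMF factors on
#' cosine similarity and retaining genes that recur across the member
#' programs' signatures.
#'
#' @slot signatures named list of character vectors (consensus signatures).
#' @slot confidence named list of named numerics in `[0, 1]`: per consensus
#'   gene, the fraction of member programs whose signature contains it.
#' @slot members named list of integer indices into the program set.
#' @slot programSet the [NmfProgramSet] the consensus was built from.
#' @slot minConfidence numeric, membership-fraction threshold.
#' @slot similarity numeric matrix of pairwise program cosine similarities.
#' @exportClass MetaprogramSet
setClass("MetaprogramSet",
  slots = c(
    signatures = "list",
    confidence = "list",
    members = "list",
    programSet = "NmfProgramSet",
    minConfidence = "numeric",
    similarity = "matrix"
  )
)

setValidity("MetaprogramSet", function(object) {
  msg <- NULL
  n <- length(object@signatures)
  if (length(object@confidence) != n || length(object@members) != n)
    msg <- c(msg, "signatures, confidence and members must have equal length")
  for (i in seq_len(n)) {
    cf <- object@confidence[[i]]
    if (any(cf < 0 | cf > 1)) { msg <- c(msg, "confidence outside [0,1]"); break }
    if (!all(object@signatures[[i]] %in% names(cf))) {
      msg <- c(msg, "signature genes missing confidence values"); break
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Gene-signature survival risk model
#'
#' Multivariate Cox model over a selected gene panel: risk score is the linear
#' predictor over per-gene standardized expression; samples are stratified at
#' the median score (strictly greater than the median is high risk).
#'
#' @slot genes character, selected gene panel.
#' @slot coefficients numeric, multivariate Cox coefficients (per standardized
#'   gene expression unit), named by gene.
#' @slot lambda numeric, LASSO penalty at which the panel was selected
#'   (`NA` if no LASSO step was run).
#' @slot center,scale numeric, per-gene standardization parameters from the
#'   training cohort, named by gene.
#' @slot scores numeric, per-sample risk scores on the training cohort.
#' @slot cutoff numeric, median training score.
#' @slot groups factor with levels `low`, `high`, per training sample.
#' @exportClass RiskModel
setClass("RiskModel",
  slots = c(
    genes = "character",
    coefficients = "numeric",
    lambda = "numeric",
    center = "numeric",
    scale = "numeric",
    scores = "numeric",
    cutoff = "numeric",
    groups = "factor"
  )
)

setValidity("RiskModel", function(object) {
  msg <- NULL
  if (length(object@genes) == 0L) msg <- c(msg, "empty gene panel")
  if (!identical(names(object@coefficients), object@genes))
    msg <- c(msg, "coefficients must be named by the gene panel")
  if (length(object@scores) != length(object@groups))
    msg <- c(msg, "scores and groups differ in length")
  if (!identical(levels(object@groups), c("low", "high")))
    msg <- c(msg, "groups must be a factor with levels low, high")
  if (length(object@scores)) {
    expected <- unname(ifelse(object@scores > object@cutoff, "high", "low"))
    if (!identical(as.character(object@groups), expected))
      msg <- c(msg, "group labels inconsistent with the median cutoff rule")
  }
  if (is.null(msg)) TRUE else msg
})

#' Survival evaluation of a risk score
#'
#' @slot logrank list with elements `chisq`, `df`, `p` from the two-group
#'   log-rank test, plus `zero_event_group` flag.
#' @slot auc named numeric, IPCW cumulative/dynamic time-dependent AUC at each
#'   horizon (names are horizons in months).
#' @slot hazardRatios [S4Vectors::DataFrame] with columns `term`, `HR`,
#'   `lower`, `upper`, `p`, `adjusted`.
#' @slot horizons numeric, evaluation horizons in months.
#' @exportClass SurvivalEval
setClass("SurvivalEval",
  slots = c(
    logrank = "list",
    auc = "numeric",
    hazardRatios = "DataFrame",
    horizons = "numeric"
  )
)

setValidity("SurvivalEval", function(object) {
  msg <- NULL
  ok <- is.na(object@auc) | (object@auc >= 0 & object@auc <= 1)
  if (!all(ok)) msg <- c(msg, "AUC values must lie in [0, 1]")
  hr <- object@hazardRatios
  if (nrow(hr)) {
    inCi <- is.na(hr$HR) | (hr$HR >= hr$lower - 1e-9 & hr$HR <= hr$upper + 1e-9)
    if (!all(inCi)) msg <- c(msg, "HR point estimate outside its CI")
  }
  if (is.null(msg)) TRUE else msg
})

#' Drug-sensitivity screen result
#'
#' @slot results [S4Vectors::DataFrame] with columns `drug_id`, `source`,
#'   `log2fc_auc`, `aggregate_r`, `passes`, sorted by `log2fc_auc` descending.
#' @slot geneCorrelations numeric matrix, risk genes x drugs, Pearson (or
#'   Spearman) correlations between gene expression and drug AUC.
#' @slot aggregate character, how per-gene correlations were aggregated
#'   (`mean`, `median`, `any`).
#' @exportClass DrugScreen
setClass("DrugScreen",
  slots = c(
    results = "DataFrame",
    geneCorrelations = "matrix",
    aggregate = "character"
  )
)

setValidity("DrugScreen", function(object) {
  msg <- NULL
  need <- c("drug_id", "source", "log2fc_auc", "aggregate_r", "passes")
  if (!all(need %in% colnames(object@results)))
    msg <- c(msg, paste("results must have columns", paste(need, collapse = ", ")))
  else {
    rs <- object@results
    expected <- rs$log2fc_auc > 0 & rs$aggregate_r < -0.05
    if (!identical(as.logical(rs$passes), as.logical(expected)))
      msg <- c(msg, "passes flag not recomputable from log2fc_auc and aggregate_r")
    if (is.unsorted(rev(rs$log2fc_auc)))
      msg <- c(msg, "results must be sorted by log2fc_auc descending")
  }
  if (is.null(msg)) TRUE else msg
})
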