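## Accessors and show() methods for the package's S4 classes.

#' @describeIn CnvProfile-accessors cells-by-genes smoothed profile matrix
#' @export
cnvMatrix <- function(x) {
  stopifnot(is(x, "CnvProfile"))
  x@profile
}

#' Accessors for CnvProfile
#'
#' @param x a [CnvProfile].
#' @return `cnvMatrix` returns the cells-by-genes matrix; `cnvGeneInfo` the
#'   chromosome-sorted gene table; `windowSize` the smoothing window width.
#' @name CnvProfile-accessors
NULL

#' @describeIn CnvProfile-accessors gene order table (gene_id, chromosome, start)
#' @export
cnvGeneInfo <- function(x) {
  stopifnot(is(x, "CnvProfile"))
  x@geneInfo
}

#' @describeIn CnvProfile-accessors smoothing window width (genes)
#' @export
windowSize <- function(x) {
  stopifnot(is(x, "CnvProfile"))
  x@windowSize
}

setMethod("show", "CnvProfile", function(object) {
  cat("CnvProfile:", nrow(object@profile), "cells x", ncol(object@profile),
      "genes\n  window:", object@windowSize, "genes; centering:",
      object@centering, "; reference-adjusted:", object@referenceAdjusted, "\n")
})

#' Accessors for MalignancyCalls
#'
#' @param x a [MalignancyCalls].
#' @return `malignancyTable` returns the per-cell DataFrame; `isMalignant` a
#'   named logical vector; `msValues`/`corrValues` named numeric vectors.
#' @name MalignancyCalls-accessors
NULL

#' @describeIn MalignancyCalls-accessors per-cell call table
#' @export
malignancyTable <- function(x) {
  stopifnot(is(x, "MalignancyCalls"))
  x@calls
}

#' @describeIn MalignancyCalls-accessors named logical malignant labels
#' @export
isMalignant <- function(x) {
  stopifnot(is(x, "MalignancyCalls"))
  stats::setNames(as.logical(x@calls$malignant), x@calls$cell_id)
}

#' @describeIn MalignancyCalls-accessors named CNV signal strength (MS)
#' @export
msValues <- function(x) {
  stopifnot(is(x, "MalignancyCalls"))
  stats::setNames(x@calls$MS, x@calls$cell_id)
}

#' @describeIn MalignancyCalls-accessors named top-set correlations (CORR)
#' @export
corrValues <- function(x) {
  stopifnot(is(x, "MalignancyCalls"))
  stats::setNames(x@calls$CORR, x@calls$cell_id)
}

setMethod("show", "MalignancyCalls", function(object) {
  n <- nrow(object@calls)
  nm <- sum(object@calls$malignant)
  cat("MalignancyCalls:", n, "cells;", nm, "malignant (",
      sprintf("%.1f%%", 100 * nm / max(1, n)), ")\n",
      "  thresholds: MS >", object@msThreshold, "| CORR >",
      object@corrThreshold, "; top fraction", object@topFraction, "\n")
})

setMethod("show", "NmfProgramSet", function(object) {
  cat("NmfProgramSet:", length(object@programs), "factor programs; ranks",
      paste(range(object@kRange), collapse = "-"), ";", object@nfeatures,
      "features/sample\n")
})

#' @describeIn MetaprogramSet-accessors consensus signatures (named list)
#' @export
signatures <- function(x) {
  stopifnot(is(x, "MetaprogramSet"))
  x@signatures
}

#' Accessors for MetaprogramSet
#'
#' @param x a [MetaprogramSet].
#' @name MetaprogramSet-accessors
#' @return `signatures` returns the named list of consensus gene vectors;
#'   `geneConfidence` the per-gene membership fractions; `programMembers` the
#'   member program indices per metaprogram.
NULL

#' @describeIn MetaprogramSet-accessors per-gene confidence per metaprogram
#' @export
geneConfidence <- function(x) {
  stopifnot(is(x, "MetaprogramSet"))
  x@confidence
}

#' @describeIn MetaprogramSet-accessors member program indices per metaprogram
#' @export
programMembers <- function(x) {
  stopifnot(is(x, "MetaprogramSet"))
  x@members
}

setMethod("show", "MetaprogramSet", function(object) {
  sizes <- lengths(object@signatures)
  cat("MetaprogramSet:", length(object@signatures), "consensus programs from",
      length(object@programSet@programs), "factor programs\n  signature sizes:",
      paste(sizes, collapse = ", "), "\n  min confidence:",
      object@minConfidence, "\n")
})

#' Accessors for RiskModel
#'
#' @param x a [RiskModel].
#' @name RiskModel-accessors
#' @return `riskGenes` returns the selected gene panel; `riskScores` the
#'   per-sample training scores; `riskGroups` the high/low stratification;
#'   `riskCutoff` the median cutoff.
NULL

#' @describeIn RiskModel-accessors selected gene panel
#' @export
riskGenes <- function(x) {
  stopifnot(is(x, "RiskModel"))
  x@genes
}

#' @describeIn RiskModel-accessors per-sample risk scores (training cohort)
#' @export
riskScores <- function(x) {
  stopifnot(is(x, "RiskModel"))
  x@scores
}

#' @describeIn RiskModel-accessors high/low risk group factor
#' @export
riskGroups <- function(x) {
  stopifnot(is(x, "RiskModel"))
  x@groups
}

#' @describeIn RiskModel-accessors median score cutoff
#' @export
riskCutoff <- function(x) {
  stopifnot(is(x, "RiskModel"))
  x@cutoff
}

#' @describeIn RiskModel-accessors multivariate Cox coefficients
#' @param object a [RiskModel].
#' @param ... unused.
#' @exportMethod coef
setMethod("coef", "RiskModel", function(object, ...) object@coefficients)

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel:", length(object@genes), "genes; lambda =",
      signif(object@lambda, 4), "\n  cutoff (median score):",
      signif(object@cutoff, 4), ";", sum(object@groups == "high"), "high /",
      sum(object@groups == "low"), "low risk samples\n")
})

#' Accessors for SurvivalEval
#'
#' @param x a [SurvivalEval].
#' @name SurvivalEval-accessors
#' @return `logrankTest` returns the log-rank chi-square/p; `timeAuc` the named
#'   per-horizon AUC vector; `hazardRatios` the HR table.
NULL

#' @describeIn SurvivalEval-accessors log-rank test (chisq, df, p)
#' @export
logrankTest <- function(x) {
  stopifnot(is(x, "SurvivalEval"))
  x@logrank
}

#' @describeIn SurvivalEval-accessors per-horizon time-dependent AUC
#' @export
timeAuc <- function(x) {
  stopifnot(is(x, "SurvivalEval"))
  x@auc
}

#' @describeIn SurvivalEval-accessors hazard-ratio table
#' @export
hazardRatios <- function(x) {
  stopifnot(is(x, "SurvivalEval"))
  x@hazardRatios
}

setMethod("show", "SurvivalEval", function(object) {
  cat("SurvivalEval: log-rank p =", signif(object@logrank$p, 3), "\n  AUC(",
      paste(names(object@auc), collapse = "/"), " mo): ",
      paste(signif(object@auc, 3), collapse = ", "), "\n", sep = "")
})

#' @describeIn DrugScreen-accessors full per-drug result table
#' @export
screenResults <- function(x) {
  stopifnot(is(x, "DrugScreen"))
  x@results
}

#' Accessors for DrugScreen
#'
#' @param x a [DrugScreen].
#' @name DrugScreen-accessors
#' @return `screenResults` returns the per-drug table; `screenHits` the IDs of
#'   drugs passing both criteria; `geneCorrelations` the gene-by-drug
#'   correlation matrix.
NULL

#' @describeIn DrugScreen-accessors drugs passing both screen criteria
#' @export
screenHits <- function(x) {
  stopifnot(is(x, "DrugScreen"))
  as.character(x@results$drug_id[x@results$passes])
}

#' @describeIn DrugScreen-accessors risk-gene by drug correlation matrix
#' @export
geneCorrelations <- function(x) {
  stopifnot(is(x, "DrugScreen"))
  x@geneCorrelations
}

setMethod("show", "DrugScreen", function(object) {
  cat("DrugScreen:", nrow(object@results), "drugs;",
      sum(object@results$passes), "pass (log2FC > 0 & r < -0.05; aggregate:",
      object@aggregate, ")\n")
})
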