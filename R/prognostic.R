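## Gene-signature risk modelling: DE intersection -> univariate Cox screen ->
## LASSO-Cox selection -> multivariate Cox risk score -> median stratification
## -> survival evaluation.

#' Wilcoxon differential expression between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value between the groups and
#' `log2FC = log2(mean_A + pc) - log2(mean_B + pc)` on the normalized scale;
#' Benjamini-Hochberg adjustment over the tested genes.
#'
#' @param mat genes x cells normalized expression matrix.
#' @param groupA,groupB character vectors of cell IDs (>= 3 cells each).
#' @param pseudocount pseudocount for the fold change (default 1).
#' @return [S4Vectors::DataFrame] with `gene_id`, `log2FC`, `p`, `p_adj`.
#' @export
deTest <- function(mat, groupA, groupB, pseudocount = 1) {
  mat <- .assertMatrix(mat)
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("both groups need at least 3 cells")
  missing <- setdiff(c(groupA, groupB), colnames(mat))
  if (length(missing))
    stop("cells absent from the matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  a <- mat[, groupA, drop = FALSE]
  b <- mat[, groupB, drop = FALSE]
  p <- vapply(seq_len(nrow(mat)), function(i) {
    suppressWarnings(stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # constant genes: no evidence
  lfc <- log2(rowMeans(a) + pseudocount) - log2(rowMeans(b) + pseudocount)
  DataFrame(gene_id = rownames(mat), log2FC = unname(lfc), p = p,
            p_adj = stats::p.adjust(p, method = "BH"),
            row.names = rownames(mat))
}

#' Intersect significant genes from two DE tables
#'
#' Genes passing `p_adj < pAdjCutoff` and `|log2FC| > lfcCutoff` in both
#' tables, sorted alphabetically. An empty intersection is allowed.
#'
#' @param deA,deB DE tables from [deTest()].
#' @param pAdjCutoff adjusted-p threshold (default 0.05).
#' @param lfcCutoff absolute log2 fold-change threshold (default 1).
#' @return sorted character vector of gene IDs.
#' @export
intersectCandidates <- function(deA, deB, pAdjCutoff = 0.05, lfcCutoff = 1) {
  pass <- function(de) {
    de$gene_id[de$p_adj < pAdjCutoff & abs(de$log2FC) > lfcCutoff]
  }
  sort(intersect(pass(deA), pass(deB)))
}

#' Univariate Cox screen over candidate genes
#'
#' Fits a proportional-hazards model per gene on standardized expression and
#' retains genes with Wald `p < pCutoff`. Genes whose fit fails to converge
#' are dropped with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param time,event survival outcome per sample (matrix column order).
#' @param genes candidate gene IDs (default: all rows).
#' @param pCutoff Wald-p threshold (default 0.05).
#' @param minEvents minimum events required in the cohort (default 10).
#' @return [S4Vectors::DataFrame] of surviving genes with `gene_id`, `HR`,
#'   `p`.
#' @export
univariateCoxScreen <- function(expr, time, event, genes = rownames(expr),
                                pCutoff = 0.05, minEvents = 10) {
  expr <- .assertMatrix(expr)
  stopifnot(length(time) == ncol(expr), length(event) == ncol(expr))
  if (sum(event) < minEvents)
    stop("fewer than ", minEvents, " events in the cohort")
  genes <- intersect(genes, rownames(expr))
  surv <- survival::Surv(time, event)
  rows <- list()
  for (g in genes) {
    x <- as.numeric(scale(expr[g, ]))
    if (all(!is.finite(x)) || stats::sd(expr[g, ]) == 0) next
    fit <- tryCatch(
      survival::coxph(surv ~ x),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit)) {
      warning("Cox fit failed for gene ", g, "; dropped")
      next
    }
    s <- summary(fit)
    p <- s$coefficients[1, "Pr(>|z|)"]
    if (is.finite(p) && p < pCutoff)
      rows[[g]] <- DataFrame(gene_id = g, HR = unname(exp(stats::coef(fit))),
                             p = p)
  }
  if (!length(rows))
    return(DataFrame(gene_id = character(0), HR = numeric(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- out$gene_id
  out
}

#' LASSO-Cox gene selection
#'
#' Fits an L1-penalized Cox path on per-gene standardized expression and
#' selects the penalty at minimum mean cross-validated partial-likelihood
#' deviance. Folds are stratified by event status with a seeded assignment.
#'
#' @param expr genes x samples expression matrix.
#' @param time,event survival outcome per sample.
#' @param genes candidate genes (>= 2).
#' @param nFolds cross-validation folds (default 10).
#' @param seed fold-assignment seed.
#' @return list with `genes` (nonzero-coefficient genes at `lambda.min`) and
#'   `lambda`.
#' @export
lassoCoxSelect <- function(expr, time, event, genes, nFolds = 10, seed = 1) {
  expr <- .assertMatrix(expr)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2L) stop("need at least 2 candidate genes")
  x <- t(scale(t(expr[genes, , drop = FALSE])))
  X <- t(x)  # samples x genes
  y <- survival::Surv(time, event)
  foldid <- .withSeed(seed, {
    id <- integer(length(time))
    for (ev in unique(event)) {
      idx <- which(event == ev)
      id[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    id
  })
  if (any(tapply(event, foldid, sum) == 0))
    warning("fold(s) without events; deviance estimates may be unstable")
  cv <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))
  selected <- rownames(beta)[beta[, 1] != 0]
  if (!length(selected))
    stop("no nonzero coefficients at lambda.min; review screening thresholds")
  list(genes = selected, lambda = cv$lambda.min)
}

#' Fit the multivariate Cox risk model
#'
#' Multivariate Cox fit on per-gene standardized expression gives the panel
#' coefficients; the per-sample risk score is the linear predictor. Samples
#' with a score strictly greater than the median are high risk, all others
#' low risk.
#'
#' @param expr genes x samples expression matrix.
#' @param time,event survival outcome per sample.
#' @param genes selected gene panel (nonempty).
#' @param lambda LASSO penalty to record (optional).
#' @return a [RiskModel].
#' @export
fitRiskModel <- function(expr, time, event, genes, lambda = NA_real_) {
  expr <- .assertMatrix(expr)
  if (length(genes) == 0L) stop("empty gene panel")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("panel genes absent from the matrix: ",
         paste(missing, collapse = ", "))
  sub <- expr[genes, , drop = FALSE]
  ctr <- rowMeans(sub)
  scl <- sqrt(.rowVars(sub))
  if (any(scl == 0)) stop("zero-variance panel gene(s)")
  z <- (sub - ctr) / scl
  df <- as.data.frame(t(z))
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df)
  beta <- stats::coef(fit)
  if (any(is.na(beta))) stop("singular design: collinear panel genes")
  if (all(abs(beta) < 1e-12)) stop("degenerate model: all coefficients zero")
  names(beta) <- genes
  scores <- drop(crossprod(z, beta))
  cutoff <- stats::median(scores)
  groups <- factor(ifelse(scores > cutoff, "high", "low"),
                   levels = c("low", "high"))
  methods::new("RiskModel", genes = genes, coefficients = beta,
               lambda = as.numeric(lambda), center = ctr, scale = scl,
               scores = scores, cutoff = cutoff, groups = groups)
}

#' Apply a risk model to a (new) expression matrix
#'
#' Standardizes with the training center/scale and scores with the stored
#' coefficients. By default samples are re-stratified at the new cohort's
#' median; set `recutoff = FALSE` to reuse the training cutoff.
#'
#' @param model a [RiskModel].
#' @param expr genes x samples expression matrix containing the panel genes.
#' @param recutoff stratify at the new median (default) or the stored cutoff.
#' @return list with `scores` and `groups`.
#' @export
applyRiskModel <- function(model, expr, recutoff = TRUE) {
  stopifnot(is(model, "RiskModel"))
  expr <- .assertMatrix(expr)
  missing <- setdiff(model@genes, rownames(expr))
  if (length(missing))
    stop("panel genes absent: ", paste(missing, collapse = ", "))
  z <- (expr[model@genes, , drop = FALSE] - model@center) / model@scale
  scores <- drop(crossprod(z, model@coefficients))
  cutoff <- if (recutoff) stats::median(scores) else model@cutoff
  groups <- factor(ifelse(scores > cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(scores = scores, groups = groups, cutoff = cutoff)
}

#' Evaluate a risk model against survival outcomes
#'
#' Kaplan-Meier comparison of the high/low groups with a two-sided log-rank
#' test, IPCW time-dependent AUC of the continuous score at the requested
#' horizons, and Cox hazard ratios of the score alone and adjusted for
#' user-supplied covariates.
#'
#' @param model a [RiskModel] fitted on this cohort (or `scores`/`groups`
#'   from [applyRiskModel()] via the `scores`/`groups` arguments).
#' @param time,event survival outcome per sample, in model score order.
#' @param horizons AUC horizons in months (default `c(24, 48, 72, 96)`).
#' @param covariates optional data.frame of adjustment covariates.
#' @param scores,groups optional explicit score/group vectors overriding the
#'   model's training values.
#' @return a [SurvivalEval].
#' @export
evaluateModel <- function(model = NULL, time, event,
                          horizons = c(24, 48, 72, 96), covariates = NULL,
                          scores = NULL, groups = NULL) {
  if (is.null(scores)) scores <- riskScores(model)
  if (is.null(groups)) groups <- riskGroups(model)
  stopifnot(length(scores) == length(time), length(groups) == length(time))
  zeroEvent <- any(tapply(event, groups, sum) == 0)
  if (zeroEvent) warning("a risk group has zero events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  lr <- list(chisq = sd$chisq, df = length(sd$n) - 1L,
             p = stats::pchisq(sd$chisq, length(sd$n) - 1L, lower.tail = FALSE),
             zero_event_group = zeroEvent)
  auc <- timeDependentAuc(scores, time, event, horizons)
  hrRow <- function(fit, term, adjusted) {
    s <- summary(fit)
    i <- match(term, rownames(s$coefficients))
    DataFrame(term = term, HR = s$coefficients[i, "exp(coef)"],
              lower = s$conf.int[i, "lower .95"],
              upper = s$conf.int[i, "upper .95"],
              p = s$coefficients[i, "Pr(>|z|)"], adjusted = adjusted)
  }
  uni <- survival::coxph(survival::Surv(time, event) ~ scores)
  hrs <- hrRow(uni, "scores", FALSE)
  if (!is.null(covariates)) {
    dat <- data.frame(scores = scores, covariates)
    adj <- survival::coxph(survival::Surv(time, event) ~ ., data = dat)
    hrs <- rbind(hrs, hrRow(adj, "scores", TRUE))
  }
  methods::new("SurvivalEval", logrank = lr, auc = auc, hazardRatios = hrs,
               horizons = as.numeric(horizons))
}

#' Survival analysis of a gene signature's mean expression
#'
#' Scores each sample by the mean expression of the matched signature genes,
#' splits at the median (strictly greater = high), and compares the groups by
#' Kaplan-Meier / log-rank.
#'
#' @param expr genes x samples bulk expression matrix.
#' @param time,event survival outcome per sample.
#' @param signature character vector of gene IDs (>= 1 matched).
#' @return list with `score`, `groups`, `logrank` (chisq, df, p).
#' @export
scoreSignatureSurvival <- function(expr, time, event, signature) {
  expr <- .assertMatrix(expr)
  matched <- intersect(signature, rownames(expr))
  if (!length(matched)) stop("no signature genes matched to the matrix")
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  score <- colMeans(expr[matched, , drop = FALSE])
  groups <- factor(ifelse(score > stats::median(score), "high", "low"),
                   levels = c("low", "high"))
  if (nlevels(droplevels(groups)) < 2L)
    stop("median split produced a single group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(score = score, groups = groups,
       logrank = list(chisq = sd$chisq, df = length(sd$n) - 1L,
                      p = stats::pchisq(sd$chisq, length(sd$n) - 1L,
                                        lower.tail = FALSE)))
}

#' End-to-end prognostic pipeline
#'
#' Univariate Cox screen over the candidate genes, LASSO-Cox selection at
#' minimum cross-validated deviance, multivariate Cox risk model, median
#' stratification, and survival evaluation.
#'
#' @param expr genes x samples expression matrix.
#' @param time,event survival outcome per sample.
#' @param candidates candidate gene IDs.
#' @param horizons AUC horizons in months.
#' @param covariates optional adjustment covariates.
#' @param nFolds,seed LASSO cross-validation parameters.
#' @return list with `screen` (univariate table), `model` (a [RiskModel]) and
#'   `eval` (a [SurvivalEval]).
#' @export
runPrognosticPipeline <- function(expr, time, event, candidates,
                                  horizons = c(24, 48, 72, 96),
                                  covariates = NULL, nFolds = 10, seed = 1) {
  screen <- univariateCoxScreen(expr, time, event, genes = candidates)
  if (nrow(screen) < 2L)
    stop("fewer than 2 genes pass the univariate screen")
  sel <- lassoCoxSelect(expr, time, event, screen$gene_id,
                        nFolds = nFolds, seed = seed)
  model <- fitRiskModel(expr, time, event, sel$genes, lambda = sel$lambda)
  eval <- evaluateModel(model, time, event, horizons = horizons,
                        covariates = covariates)
  list(screen = screen, model = model, eval = eval)
}
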