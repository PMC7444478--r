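## Normalization, variance stabilization, the self-contained NB exact
## test, FDR control, and the qPCR fold-change utility.

#' Counts per million
#'
#' `value(g, s) = counts(g, s) / total(s) * 1e6`; every column of the
#' result sums to one million.
#'
#' @param x A [MicrogliaExperiment-class] or a non-negative count matrix
#'   with sample columns.
#' @return Numeric matrix of CPM values with the input dimnames.
#' @export
#' @examples
#' cpm(matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1")))
setGeneric("cpm", function(x) standardGeneric("cpm"))

#' @rdname cpm
#' @export
setMethod("cpm", "matrix", function(x) {
  totals <- colSums(x)
  if (any(totals == 0)) {
    bad <- colnames(x)[totals == 0]
    if (is.null(bad)) bad <- which(totals == 0)
    stop("sample '", bad[1], "' has zero total count")
  }
  sweep(x, 2, totals, "/") * 1e6
})

#' @rdname cpm
#' @export
setMethod("cpm", "MicrogliaExperiment", function(x) cpm(assay(x, "counts")))

#' Variance-stabilizing transform
#'
#' `log2(CPM + priorCount)`: a log transform with a pseudo-count that
#' removes most of the mean dependence of the variance of NB counts, used
#' before distance-based sample-separation analyses.
#'
#' @param x A [MicrogliaExperiment-class] or count matrix.
#' @param priorCount Positive pseudo-count added before the log (default
#'   1, so zero counts map to 0).
#' @return Numeric matrix of transformed values.
#' @export
setGeneric("vst", function(x, priorCount = 1) standardGeneric("vst"))

#' @rdname vst
#' @export
setMethod("vst", "matrix", function(x, priorCount = 1) {
  .assertScalarNumber(priorCount, "priorCount", lower = 0, strictLower = TRUE)
  log2(cpm(x) + priorCount)
})

#' @rdname vst
#' @export
setMethod("vst", "MicrogliaExperiment", function(x, priorCount = 1)
  vst(assay(x, "counts"), priorCount))

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment (via [stats::p.adjust]) with input validation;
#' order-preserving with the input vector.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @export
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
bhFDR <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must be finite and within [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' qPCR relative quantification (2^-ddCt)
#'
#' Fold change of a target transcript in a treated condition relative to
#' control, normalized to a reference gene:
#' `2^-((ctTargetTreated - ctRefTreated) - (ctTargetControl - ctRefControl))`.
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetControl,ctRefControl
#'   Finite quantification-cycle (Ct) values.
#' @return Positive fold change.
#' @export
#' @examples
#' ddct(20, 18, 22, 18)  # one extra doubling relative to control
ddct <- function(ctTargetTreated, ctRefTreated, ctTargetControl,
                 ctRefControl) {
  vals <- c(ctTargetTreated, ctRefTreated, ctTargetControl, ctRefControl)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  2^-((ctTargetTreated - ctRefTreated) - (ctTargetControl - ctRefControl))
}

#' Pooled moment estimator of the common NB dispersion
#'
#' With variance `mu + phi mu^2`, `E[s^2 - m] = phi mu^2` within a
#' replicate group; the estimator pools `(s^2 - m)` and `m^2` across all
#' genes and groups, weighted by within-group degrees of freedom, and
#' truncates at zero.
#'
#' @param counts Numeric matrix (genes x samples), depth-equalized.
#' @param groups Factor/character of group labels, one per column.
#' @return Non-negative dispersion estimate `phi`.
#' @export
estimateCommonDispersion <- function(counts, groups) {
  groups <- as.factor(groups)
  num <- 0; den <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- counts[, idx, drop = FALSE]
    m <- rowMeans(sub)
    v <- .rowVars(sub)
    w <- length(idx) - 1
    num <- num + w * sum(v - m)
    den <- den + w * sum(m^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

## Conditional two-sided NB exact test for one gene: probability mass of
## all splits of the total whose probability does not exceed that of the
## observed split. phi ~ 0 reduces to the conditional binomial.
.nbExactPValue <- function(sRef, sAlt, nRef, nAlt, phi) {
  total <- sRef + sAlt
  if (total == 0) return(1)
  lambda <- total / (nRef + nAlt)
  ## enumerate within a generous window around the conditional mean for
  ## large totals; mass outside the window is counted as more extreme
  if (total <= 20000) {
    y <- 0:total
  } else {
    center <- total * nAlt / (nRef + nAlt)
    s <- sqrt(center * (1 + phi * lambda * nAlt)) + 1
    lo <- max(0, floor(center - 50 * s)); hi <- min(total, ceiling(center + 50 * s))
    y <- seq(min(lo, sAlt), max(hi, sAlt))
  }
  f <- if (phi < 1e-10) {
    dbinom(y, total, nAlt / (nRef + nAlt))
  } else {
    dnbinom(y, size = nAlt / phi, mu = nAlt * lambda) *
      dnbinom(total - y, size = nRef / phi, mu = nRef * lambda)
  }
  ## the joint mass over splits sums to P(total); dividing by it gives the
  ## conditional distribution (window truncation drops negligible tails)
  tot <- sum(f)
  fObs <- f[match(sAlt, y)]
  p <- sum(f[f <= fObs * (1 + 1e-10)]) / tot
  min(1, p)
}

#' Common-dispersion negative-binomial exact test (KI vs WT, one stage)
#'
#' A self-contained differential-expression test in the exact
#' conditional NB family: library sizes are equalized by scaling each
#' sample to the geometric-mean depth, a single common dispersion is
#' estimated by a pooled moment estimator
#' ([estimateCommonDispersion()]), and per gene the two-sided conditional
#' probability of the KI count sum given the total is computed. Log2
#' fold changes (KI over WT) use normalized group means with a 0.5
#' pseudo-count; FDR by [bhFDR()].
#'
#' @param x A [MicrogliaExperiment-class].
#' @param stage One of [stageLevels()]; the stage must have at least two
#'   WT and two KI samples.
#' @param filter Keep only genes with CPM > `minCPM` in at least
#'   `minSamples` of the stage's samples (default on).
#' @param minCPM,minSamples Low-count filter parameters.
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`, `fdr`,
#'   `stage`.
#' @export
setGeneric("nbExactTest", function(x, stage, filter = TRUE, minCPM = 1,
                                   minSamples = 2) standardGeneric("nbExactTest"))

#' @rdname nbExactTest
#' @export
setMethod("nbExactTest", "MicrogliaExperiment",
          function(x, stage, filter = TRUE, minCPM = 1, minSamples = 2) {
  stage <- match.arg(stage, .STAGES)
  cd <- colData(x)
  sel <- cd$stage == stage
  counts <- assay(x, "counts")[, sel, drop = FALSE]
  genotype <- cd$genotype[sel]
  if (sum(genotype == "WT") < 2 || sum(genotype == "KI") < 2)
    stop("stage '", stage, "' needs >= 2 replicates per genotype")
  if (filter) {
    cp <- cpm(counts)
    keep <- rowSums(cp > minCPM) >= minSamples
    counts <- counts[keep, , drop = FALSE]
  }
  libs <- colSums(counts)
  geo <- exp(mean(log(libs)))
  scaled <- round(sweep(counts, 2, geo / libs, "*"))
  phi <- estimateCommonDispersion(scaled, genotype)
  wt <- genotype == "WT"; ki <- genotype == "KI"
  nW <- sum(wt); nK <- sum(ki)
  sW <- rowSums(scaled[, wt, drop = FALSE])
  sK <- rowSums(scaled[, ki, drop = FALSE])
  pvals <- vapply(seq_along(sW), function(i)
    .nbExactPValue(sW[i], sK[i], nW, nK, phi), numeric(1))
  log2fc <- log2((sK / nK + 0.5) / (sW / nW + 0.5))
  data.frame(gene = rownames(counts), log2fc = log2fc, pvalue = pvals,
             fdr = bhFDR(pvals), stage = stage, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Per-stage differential expression for several stages at once
#'
#' Convenience wrapper running [nbExactTest()] for each requested stage.
#'
#' @param x A [MicrogliaExperiment-class].
#' @param stages Character vector of stages (default all four).
#' @param ... Passed to [nbExactTest()].
#' @return Named list of DE data.frames.
#' @export
deByStage <- function(x, stages = stageLevels(), ...) {
  setNames(lapply(stages, function(st) nbExactTest(x, st, ...)), stages)
}
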