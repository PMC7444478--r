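## Distance-based genotype-separation analysis: MDS, the mean
## cross-genotype distance contrast, its Phipson-Smyth permutation test,
## gene-subsampling robustness, and the signature-restricted variants.

#' Euclidean distances between samples
#'
#' @param expr Numeric matrix (genes x samples) of finite expression
#'   values (typically [vst()] output).
#' @return A [stats::dist] object over samples.
#' @export
euclideanDistances <- function(expr) {
  if (ncol(expr) < 2) stop("need at least 2 samples")
  if (any(!is.finite(expr))) stop("expression values must be finite")
  dist(t(expr), method = "euclidean")
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centered Gram eigendecomposition via [stats::cmdscale];
#' coordinates come from the top-`k` non-negative eigenvalues. Negative
#' eigenvalues beyond tolerance (non-Euclidean input) are reported with
#' a warning while the non-negative part is still returned.
#'
#' @param d A [stats::dist] or symmetric distance matrix.
#' @param k Embedding dimension (`<= samples - 1`), default 3 for the
#'   usual 3D sample map.
#' @param tol Tolerance for flagging negative eigenvalues.
#' @return list with `points` (sample x k), `eig` (all eigenvalues) and
#'   `nNegative`.
#' @export
classicalMDS <- function(d, k = 3, tol = 1e-8) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (k > n - 1) stop("k must be <= samples - 1")
  scale <- max(dm)
  res <- suppressWarnings(cmdscale(dm, k = k, eig = TRUE))
  nNeg <- sum(res$eig < -tol * max(scale^2, 1))
  if (nNeg > 0)
    warning(nNeg, " negative eigenvalue(s): input is not Euclidean")
  pts <- res$points
  if (ncol(pts) < k) {  # pad when trailing eigenvalues are not positive
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    rownames(pts) <- rownames(dm)
  }
  colnames(pts) <- paste0("MDS", seq_len(k))
  list(points = pts, eig = res$eig, nNegative = nNeg)
}

.stageGenotypeIdx <- function(design, stage, genotype) {
  which(design$stage == stage & design$genotype == genotype)
}

## mean Euclidean distance over all cross-genotype sample pairs in a stage
.meanCrossDist <- function(expr, idxA, idxB) {
  tot <- 0
  for (i in idxA) for (j in idxB)
    tot <- tot + sqrt(sum((expr[, i] - expr[, j])^2))
  tot / (length(idxA) * length(idxB))
}

.checkContrast <- function(design, focal, reference) {
  for (st in c(focal, reference)) for (gt in .GENOTYPES)
    if (!length(.stageGenotypeIdx(design, st, gt)))
      stop("stage '", st, "' is missing genotype '", gt, "'")
}

#' Genotype-separation contrast statistic
#'
#' `meanDist(WT, KI | focal stage) - meanDist(WT, KI | reference stage)`,
#' each term the mean Euclidean distance over all cross-genotype sample
#' pairs within the stage. Large positive values mean the genotypes are
#' farther apart in the focal stage than in the reference stage.
#'
#' @param expr Numeric matrix (genes x samples), columns named by sample.
#' @param design Sample design data.frame (see [makeDesign()]).
#' @param focal,reference Stage names; both must contain both genotypes.
#' @return Numeric statistic.
#' @export
separationStatistic <- function(expr, design, focal, reference) {
  focal <- match.arg(focal, .STAGES); reference <- match.arg(reference, .STAGES)
  .checkContrast(design, focal, reference)
  expr <- expr[, design$sample_id, drop = FALSE]
  .meanCrossDist(expr, .stageGenotypeIdx(design, focal, "WT"),
                 .stageGenotypeIdx(design, focal, "KI")) -
    .meanCrossDist(expr, .stageGenotypeIdx(design, reference, "WT"),
                   .stageGenotypeIdx(design, reference, "KI"))
}

#' Permutation test of the separation contrast (Phipson-Smyth p-value)
#'
#' Each of the `nPerm` permutations independently shuffles every gene's
#' values across all samples — destroying stage and genotype structure
#' while preserving each gene's marginal — and recomputes the contrast.
#' The p-value is `(b + 1) / (nPerm + 1)` with `b` the number of
#' permutation statistics greater than or equal to the observed one, so
#' it is bounded below by `1 / (nPerm + 1)`.
#'
#' @inheritParams separationStatistic
#' @param x For the `MicrogliaExperiment` method, the experiment;
#'   expression is taken as `vst(x)`.
#' @param nPerm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param ... passed through to the matrix method.
#' @return A [PermutationTestResult-class].
#' @export
setGeneric("permutationTest",
           function(x, design, focal, reference, nPerm = 1000, seed = 1, ...)
             standardGeneric("permutationTest"))

#' @rdname permutationTest
#' @export
setMethod("permutationTest", "matrix",
          function(x, design, focal, reference, nPerm = 1000, seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  observed <- separationStatistic(x, design, focal, reference)
  expr <- x[, design$sample_id, drop = FALSE]
  wf <- .stageGenotypeIdx(design, focal, "WT") - 1L
  kf <- .stageGenotypeIdx(design, focal, "KI") - 1L
  wr <- .stageGenotypeIdx(design, reference, "WT") - 1L
  kr <- .stageGenotypeIdx(design, reference, "KI") - 1L
  set.seed(as.integer(seed))
  perms <- .permSepStats(expr, wf, kf, wr, kr, as.integer(nPerm))
  b <- sum(perms >= observed)
  new("PermutationTestResult", observed = observed, b = as.integer(b),
      nPerm = as.integer(nPerm), pvalue = (b + 1) / (nPerm + 1),
      seed = as.integer(seed))
})

#' @rdname permutationTest
#' @export
setMethod("permutationTest", "MicrogliaExperiment",
          function(x, design, focal, reference, nPerm = 1000, seed = 1, ...) {
  if (missing(design)) design <- sampleDesign(x)
  permutationTest(vst(x), design, focal, reference, nPerm, seed)
})

#' Gene-subsampling robustness of the permutation test
#'
#' Repeats the permutation test on `nReps` independent uniform gene
#' subsets of size `nGenes` (defaults: 5000 genes, 100 repeats), to rule
#' out a handful of genes driving the separation. Each replicate draws
#' its genes and its permutation stream from deterministic child seeds of
#' the master seed.
#'
#' @inheritParams permutationTest
#' @param expr Numeric matrix (genes x samples).
#' @param nGenes Subset size (`<=` available genes).
#' @param nReps Number of replicates.
#' @return list with `pvalues` (length `nReps`) and their `median`.
#' @export
subsampleRobustness <- function(expr, design, focal, reference,
                                nGenes = 5000, nReps = 100, nPerm = 1000,
                                seed = 1) {
  if (nGenes > nrow(expr)) stop("nGenes exceeds the available genes")
  pv <- numeric(nReps)
  for (r in seq_len(nReps)) {
    set.seed(.childSeed(seed, 2L * r - 1L))
    idx <- sort(sample(nrow(expr), nGenes))
    res <- permutationTest(expr[idx, , drop = FALSE], design, focal,
                           reference, nPerm, seed = .childSeed(seed, 2L * r))
    pv[r] <- res@pvalue
  }
  list(pvalues = pv, median = median(pv))
}

#' Signature-restricted permutation test
#'
#' Restricts the matrix to the identity-signature genes (no subsampling:
#' the set is small, e.g. the six-gene signature) and runs
#' [permutationTest()].
#'
#' @inheritParams permutationTest
#' @param expr Numeric matrix (genes x samples).
#' @param signature Character vector of signature genes; the intersection
#'   with the expressed genes must be non-empty.
#' @return A [PermutationTestResult-class].
#' @export
signatureTest <- function(expr, design, signature, focal, reference,
                          nPerm = 1000, seed = 1) {
  genes <- intersect(rownames(expr), signature)
  if (!length(genes)) stop("signature does not intersect the expressed genes")
  permutationTest(expr[genes, , drop = FALSE], design, focal, reference,
                  nPerm, seed)
}

#' Signature-restricted principal component analysis
#'
#' Centered (by default unscaled) PCA of the samples on the
#' signature-restricted expression matrix.
#'
#' @param expr Numeric matrix (genes x samples).
#' @param signature Character vector of signature genes; at least `k`
#'   must be present.
#' @param k Number of components.
#' @param scale. Scale genes to unit variance before PCA (default
#'   FALSE).
#' @return list with `scores` (sample x k), `explained`
#'   (variance fractions, sum <= 1) and `sdev`.
#' @export
signaturePCA <- function(expr, signature, k = 3, scale. = FALSE) {
  genes <- intersect(rownames(expr), signature)
  if (length(genes) < k)
    stop("k exceeds the number of signature genes present")
  sub <- t(expr[genes, , drop = FALSE])
  pc <- prcomp(sub, center = TRUE, scale. = scale.)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(k, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)], sdev = pc$sdev)
}
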