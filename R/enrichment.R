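## Parametric gene-set enrichment (PAGE) and the TF-target
## differential-expression statistics.

#' PAGE enrichment z-score for one gene set
#'
#' `z = (Sm - mu) * sqrt(m) / delta` where `Sm` is the mean score of the
#' set members present in the scored universe, `mu` the global mean and
#' `delta` the global population standard deviation; the two-sided
#' p-value comes from the standard normal.
#'
#' @param scores Named numeric vector of per-gene scores (>= 2 genes,
#'   non-zero spread).
#' @param members Character vector of member gene ids.
#' @return list with `z`, `pvalue` and `m` (member overlap with the
#'   scored universe). Zero overlap is flagged by `m = 0` with `NA`
#'   statistics, not by `z = 0`.
#' @export
#' @examples
#' s <- setNames(1:6, paste0("g", 1:6))
#' pageZScore(s, c("g4", "g5", "g6"))
pageZScore <- function(scores, members) {
  if (length(scores) < 2 || is.null(names(scores)))
    stop("scores must be a named vector of length >= 2")
  mu <- mean(scores)
  delta <- sqrt(mean((scores - mu)^2))  # population SD, PAGE's original form
  if (delta == 0) stop("scores have zero spread")
  members <- intersect(members, names(scores))
  m <- length(members)
  if (m == 0)
    return(list(z = NA_real_, pvalue = NA_real_, m = 0L))
  z <- (mean(scores[members]) - mu) * sqrt(m) / delta
  list(z = z, pvalue = 2 * pnorm(-abs(z)), m = m)
}

## per-gene score fed to PAGE: signed significance by default
.deScores <- function(de, scoreType = c("signed_logp", "log2fc")) {
  scoreType <- match.arg(scoreType)
  if (scoreType == "signed_logp") {
    p <- pmax(de$pvalue, 1e-300)
    setNames(sign(de$log2fc) * -log10(p), de$gene)
  } else setNames(de$log2fc, de$gene)
}

#' PAGE enrichment of a gene-set collection against DE results
#'
#' Scores each gene by its signed DE significance
#' (`sign(log2fc) * -log10(pvalue)`, or `log2fc` if requested), applies
#' the set-size filter after intersection with the scored universe, and
#' adjusts over the tested sets with [bhFDR()]. `rank_score` is
#' `sign(z) * -log10(pvalue)`, so up/down regulation carries the sign.
#'
#' @param de DE data.frame from [nbExactTest()].
#' @param sets A [GeneSetCollection-class].
#' @param sizeMin,sizeMax Inclusive set-size filter (default 10–500);
#'   sets outside it after intersection are excluded.
#' @param scoreType `"signed_logp"` (default) or `"log2fc"`.
#' @return data.frame (`set_name`, `z`, `pvalue`, `fdr`, `rank_score`,
#'   `m`) sorted by decreasing `rank_score`; empty (with a warning) if
#'   every set is filtered out.
#' @export
pageEnrich <- function(de, sets, sizeMin = 10, sizeMax = 500,
                       scoreType = c("signed_logp", "log2fc")) {
  scores <- .deScores(de, match.arg(scoreType))
  if (length(scores) < sizeMin)
    stop("DE results cover fewer genes than sizeMin")
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(scores))
    m <- length(members)
    if (m < sizeMin || m > sizeMax) return(NULL)
    r <- pageZScore(scores, members)
    data.frame(set_name = nm, z = r$z, pvalue = r$pvalue, m = r$m,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    warning("all sets were removed by the size filter")
    return(data.frame(set_name = character(), z = numeric(),
                      pvalue = numeric(), fdr = numeric(),
                      rank_score = numeric(), m = integer()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bhFDR(out$pvalue)
  out$rank_score <- sign(out$z) * -log10(pmax(out$pvalue, 1e-300))
  out <- out[order(out$rank_score, decreasing = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("set_name", "z", "pvalue", "fdr", "rank_score", "m")]
}

#' Fraction of TF targets differentially expressed, per TF and stage
#'
#' For each regulon and stage, the fraction of tested targets with
#' `fdr < fdrCut`. A regulon with zero tested targets in a stage is
#' reported as missing (`NA`), not as zero. Optionally aggregates over a
#' named TF subset (pooling their target genes per stage).
#'
#' @param deByStage Named list of DE data.frames (one per stage).
#' @param regulons A [GeneSetCollection-class] of TF target sets.
#' @param fdrCut FDR threshold in (0, 1] (default 0.1).
#' @param aggregateTFs Optional character vector of regulon names to
#'   pool; the pooled per-stage fractions are attached as
#'   `attr(result, "aggregate")`.
#' @return data.frame with columns `tf`, `stage`, `nTested`, `nDE`,
#'   `fraction`.
#' @export
tfTargetFraction <- function(deByStage, regulons, fdrCut = 0.1,
                             aggregateTFs = NULL) {
  .assertScalarNumber(fdrCut, "fdrCut", lower = 0, upper = 1,
                      strictLower = TRUE)
  out <- do.call(rbind, lapply(names(regulons), function(tf) {
    targets <- regulons[[tf]]
    do.call(rbind, lapply(names(deByStage), function(st) {
      de <- deByStage[[st]]
      tested <- de[de$gene %in% targets, , drop = FALSE]
      n <- nrow(tested)
      nDE <- sum(tested$fdr < fdrCut)
      data.frame(tf = tf, stage = st, nTested = n, nDE = nDE,
                 fraction = if (n > 0) nDE / n else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  if (!is.null(aggregateTFs)) {
    agg <- do.call(rbind, lapply(names(deByStage), function(st) {
      de <- deByStage[[st]]
      targets <- unique(unlist(geneSets(regulons)[aggregateTFs]))
      tested <- de[de$gene %in% targets, , drop = FALSE]
      n <- nrow(tested)
      data.frame(stage = st, nTested = n, nDE = sum(tested$fdr < fdrCut),
                 fraction = if (n > 0) sum(tested$fdr < fdrCut) / n
                            else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(agg) <- NULL
    attr(out, "aggregate") <- agg
  }
  out
}

#' TF-by-stage PAGE z-score matrix
#'
#' Entry `(t, s)` is the PAGE z-score of regulon `t` against stage `s`'s
#' signed DE statistic — the TF-activity heatmap across development.
#' Untestable cells (zero overlap with the tested genes) are `NA`.
#'
#' @param deByStage Named list of DE data.frames.
#' @param regulons A [GeneSetCollection-class].
#' @param scoreType Passed to the per-gene scoring (see [pageEnrich()]).
#' @return Numeric matrix (TF x stage) with fixed row/column order.
#' @export
tfZMatrix <- function(deByStage, regulons,
                      scoreType = c("signed_logp", "log2fc")) {
  scoreType <- match.arg(scoreType)
  tfs <- names(regulons)
  stages <- names(deByStage)
  z <- matrix(NA_real_, length(tfs), length(stages),
              dimnames = list(tfs, stages))
  for (st in stages) {
    scores <- .deScores(deByStage[[st]], scoreType)
    for (tf in tfs) {
      r <- pageZScore(scores, regulons[[tf]])
      z[tf, st] <- r$z
    }
  }
  z
}
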