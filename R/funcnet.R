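## Tissue-context functional network: gold standard from expression
## rules, naive-Bayes integration of binned evidence, thresholding,
## neighborhood / TF-linking queries, cross-validation, DE
## recapitulation, ortholog mapping.

#' Context-expressed genes from CPM rules
#'
#' Genes with mean CPM strictly above `highCut` in the brain-rudiment
#' samples and strictly below `lowCut` in the adult samples (the
#' developmental-context expression rule), united with any supplied
#' comparative sets (genes highly expressed in microglia relative to
#' other cell types).
#'
#' @param rudimentCPM,adultCPM CPM matrices (genes x samples) sharing a
#'   gene universe.
#' @param highCut,lowCut Strict CPM cutoffs (defaults 50 and 10).
#' @param comparativeSets list of character vectors to union in.
#' @return Sorted character vector of context genes.
#' @export
contextGenes <- function(rudimentCPM, adultCPM, highCut = 50, lowCut = 10,
                         comparativeSets = list()) {
  if (!identical(rownames(rudimentCPM), rownames(adultCPM)))
    stop("matrices must share a gene universe (identical rownames)")
  core <- rownames(rudimentCPM)[rowMeans(rudimentCPM) > highCut &
                                  rowMeans(adultCPM) < lowCut]
  sort(unique(c(core, unlist(comparativeSets))))
}

#' Build a training gold standard of positive and negative gene pairs
#'
#' Positives are known-interaction pairs whose two members are both
#' context-expressed. Negatives are sampled from the pair universe among
#' pairs that are (a) not known interactions, or (b) have at least one
#' member outside the context, at a configurable negative:positive
#' ratio.
#'
#' @param context Character vector of context-expressed genes.
#' @param knownPairs Character vector of canonical pair keys with known
#'   functional interactions.
#' @param pairUniverse Character vector of canonical pair keys to draw
#'   negatives from.
#' @param negativesPerPositive Negative:positive ratio (default 19, the
#'   rare-positive regime typical of functional gold standards).
#' @param seed Integer RNG seed for negative sampling.
#' @return A [GoldStandard-class].
#' @export
buildGoldStandard <- function(context, knownPairs, pairUniverse,
                              negativesPerPositive = 19, seed = 1) {
  knownPairs <- unique(knownPairs)
  ab <- splitPairKey(knownPairs)
  inContext <- ab[, 1] %in% context & ab[, 2] %in% context
  positives <- sort(knownPairs[inContext])
  if (!length(positives))
    stop(sprintf(paste0("no positive pairs: %d known pairs, %d context ",
                        "genes, 0 pairs fully inside the context"),
                 length(knownPairs), length(context)))
  uni <- unique(pairUniverse)
  uab <- splitPairKey(uni)
  outside <- !(uab[, 1] %in% context) | !(uab[, 2] %in% context)
  candidates <- uni[!(uni %in% knownPairs) | outside]
  candidates <- setdiff(candidates, positives)
  if (!length(candidates))
    stop("no candidate negatives in the pair universe")
  nNeg <- round(negativesPerPositive * length(positives))
  set.seed(as.integer(seed))
  negatives <- if (nNeg >= length(candidates)) {
    warning("fewer candidate negatives than requested; using all")
    sort(candidates)
  } else sort(sample(candidates, nNeg))
  new("GoldStandard", positives = positives, negatives = negatives,
      contextGenes = sort(unique(context)))
}

#' Quantile-discretise evidence datasets
#'
#' Per dataset, interior quantile edges are computed on the observed
#' scores and every scored pair is mapped to a bin in `1..nBins`; pairs
#' a dataset does not cover map to the reserved missing bin
#' `nBins + 1`. A constant-score dataset collapses to a single usable
#' bin (warned).
#'
#' @param evidence An [EvidenceCollection-class].
#' @param nBins Number of observed-score bins (>= 2).
#' @return A [BinnedEvidence-class].
#' @export
binEvidence <- function(evidence, nBins = 5) {
  if (nBins < 2) stop("nBins must be >= 2")
  bins <- list(); edges <- list()
  for (nm in names(evidence)) {
    d <- evidenceDatasets(evidence)[[nm]]
    qs <- quantile(d$score, probs = seq_len(nBins - 1) / nBins,
                   names = FALSE, type = 7)
    qs <- unique(qs)
    if (length(qs) < nBins - 1 && length(unique(d$score)) == 1) {
      warning("dataset '", nm, "' has constant scores: single usable bin")
      qs <- numeric(0)
    }
    idx <- findInterval(d$score, qs, left.open = TRUE) + 1L
    bins[[nm]] <- setNames(as.integer(idx), pairKey(d$geneA, d$geneB))
    edges[[nm]] <- qs
  }
  new("BinnedEvidence", bins = bins, binEdges = edges,
      nBins = as.integer(nBins))
}

.pairBins <- function(binned, dataset, pairs) {
  b <- binned@bins[[dataset]][pairs]
  b[is.na(b)] <- binned@nBins + 1L
  as.integer(b)
}

#' Train the naive-Bayes evidence-integration classifier
#'
#' `priorOdds = |positives| / |negatives|`; per dataset, `P(bin | class)`
#' is estimated on the gold-standard pairs with additive (Laplace)
#' smoothing `alpha` over the `nBins + 1` bins (missing evidence is a
#' bin, so absent measurements are themselves informative). A dataset in
#' which every gold pair is missing is dropped with a warning.
#'
#' @param gold A [GoldStandard-class].
#' @param binned A [BinnedEvidence-class].
#' @param alpha Positive smoothing pseudocount (default 1).
#' @return A [NaiveBayesModel-class].
#' @export
trainNaiveBayes <- function(gold, binned, alpha = 1) {
  .assertScalarNumber(alpha, "alpha", lower = 0, strictLower = TRUE)
  pos <- positivePairs(gold); neg <- negativePairs(gold)
  if (!length(pos) || !length(neg))
    stop("both gold-standard classes must be non-empty")
  nb <- binned@nBins + 1L
  tables <- list(); edges <- list()
  for (nm in names(binned@bins)) {
    bp <- .pairBins(binned, nm, pos)
    bn <- .pairBins(binned, nm, neg)
    if (all(bp == nb) && all(bn == nb)) {
      warning("dataset '", nm, "' covers no gold-standard pairs: dropped")
      next
    }
    cp <- tabulate(bp, nbins = nb); cn <- tabulate(bn, nbins = nb)
    tables[[nm]] <- rbind(pos = (cp + alpha) / (length(pos) + alpha * nb),
                          neg = (cn + alpha) / (length(neg) + alpha * nb))
    colnames(tables[[nm]]) <- c(paste0("bin", seq_len(binned@nBins)),
                                "missing")
    edges[[nm]] <- binned@binEdges[[nm]]
  }
  new("NaiveBayesModel", priorOdds = length(pos) / length(neg),
      tables = tables, binEdges = edges, nBins = binned@nBins,
      alpha = alpha)
}

#' Score gene pairs with a trained model
#'
#' `posteriorOdds(pair) = priorOdds * prod_d P(bin_d | pos) / P(bin_d |
#' neg)`. A pair with all-missing evidence is scored through the
#' missing-bin ratios, never skipped.
#'
#' @param model A [NaiveBayesModel-class].
#' @param binned A [BinnedEvidence-class] (the same discretisation used
#'   in training).
#' @param pairs Character vector of canonical pair keys to score.
#' @return A [FunctionalNetwork-class].
#' @export
scorePairs <- function(model, binned, pairs) {
  pairs <- unique(pairs)
  logOdds <- rep(log(model@priorOdds), length(pairs))
  for (nm in names(model@tables)) {
    b <- .pairBins(binned, nm, pairs)
    tb <- model@tables[[nm]]
    logOdds <- logOdds + log(tb["pos", b]) - log(tb["neg", b])
  }
  ab <- splitPairKey(pairs)
  FunctionalNetwork(
    data.frame(geneA = ab[, 1], geneB = ab[, 2],
               posteriorOdds = exp(logOdds),
               foldOverPrior = exp(logOdds) / model@priorOdds,
               stringsAsFactors = FALSE),
    priorOdds = model@priorOdds)
}

#' Keep only strong functional interactions
#'
#' Retains edges with `foldOverPrior >= minFoldOverPrior` (inclusive; an
#' edge at exactly the cutoff stays). The default 5 keeps the
#' "five-fold over prior" interactions.
#'
#' @param net A [FunctionalNetwork-class].
#' @param minFoldOverPrior Positive cutoff (default 5).
#' @return Thresholded [FunctionalNetwork-class].
#' @export
thresholdNetwork <- function(net, minFoldOverPrior = 5) {
  .assertScalarNumber(minFoldOverPrior, "minFoldOverPrior", lower = 0,
                      strictLower = TRUE)
  e <- networkEdges(net)
  FunctionalNetwork(e[e$foldOverPrior >= minFoldOverPrior, , drop = FALSE],
                    priorOdds = net@priorOdds, metadata = net@metadata)
}

#' Top network neighbors of a seed gene
#'
#' The `k` genes with the highest posterior-odds edges to the seed
#' (default 25, the size of the published seed-gene neighborhood); ties
#' broken lexicographically, fewer returned if the seed has fewer
#' partners.
#'
#' @param net A [FunctionalNetwork-class].
#' @param seedGene Gene id present in the network's pair universe.
#' @param k Number of neighbors (default 25).
#' @return data.frame with columns `gene`, `posteriorOdds`, ranked.
#' @export
topNeighbors <- function(net, seedGene, k = 25) {
  e <- networkEdges(net)
  hit <- e$geneA == seedGene | e$geneB == seedGene
  if (!(seedGene %in% c(e$geneA, e$geneB)))
    stop("seed gene '", seedGene, "' is not in the network")
  sub <- e[hit, , drop = FALSE]
  partner <- ifelse(sub$geneA == seedGene, sub$geneB, sub$geneA)
  ord <- order(-sub$posteriorOdds, partner)
  out <- data.frame(gene = partner[ord],
                    posteriorOdds = sub$posteriorOdds[ord],
                    stringsAsFactors = FALSE)
  head(out, k)
}

#' Link a seed-gene neighborhood to transcription factors
#'
#' For each TF, returns the neighborhood genes from which the TF is
#' reachable within `maxSteps` edges of the (thresholded) network,
#' with one shortest path each — the candidate genes linking the seed
#' gene to the TF. A TF absent from the network is reported unreachable,
#' not an error.
#'
#' @param net A thresholded [FunctionalNetwork-class].
#' @param neighborhood Character vector of neighborhood genes.
#' @param tfs Character vector of TF gene ids.
#' @param maxSteps Maximum path length in edges (default 2).
#' @return Named list (one element per TF) of data.frames with columns
#'   `gene`, `steps`, `path` (genes joined by `"->"`); zero rows when
#'   unreachable.
#' @export
linkTFs <- function(net, neighborhood, tfs, maxSteps = 2) {
  if (maxSteps < 1) stop("maxSteps must be >= 1")
  e <- networkEdges(net)
  g <- igraph::graph_from_data_frame(e[, c("geneA", "geneB")],
                                     directed = FALSE)
  verts <- igraph::V(g)$name
  empty <- data.frame(gene = character(), steps = integer(),
                      path = character(), stringsAsFactors = FALSE)
  out <- setNames(vector("list", length(tfs)), tfs)
  for (tf in tfs) {
    if (!(tf %in% verts)) { out[[tf]] <- empty; next }
    nbPresent <- intersect(neighborhood, verts)
    nbPresent <- setdiff(nbPresent, tf)
    if (!length(nbPresent)) { out[[tf]] <- empty; next }
    dvec <- as.vector(igraph::distances(g, v = tf, to = nbPresent))
    keep <- which(is.finite(dvec) & dvec <= maxSteps & dvec >= 1)
    if (!length(keep)) { out[[tf]] <- empty; next }
    reach <- nbPresent[keep]
    paths <- igraph::shortest_paths(g, from = tf, to = reach)$vpath
    out[[tf]] <- data.frame(
      gene = reach, steps = as.integer(dvec[keep]),
      path = vapply(paths, function(p) paste(rev(names(p)), collapse = "->"),
                    character(1)),
      stringsAsFactors = FALSE)
    out[[tf]] <- out[[tf]][order(out[[tf]]$steps, out[[tf]]$gene), ,
                           drop = FALSE]
    rownames(out[[tf]]) <- NULL
  }
  out
}

#' Cross-validate the evidence-integration classifier
#'
#' Pair-level stratified fold assignment; each fold's model is trained
#' with the held-out pairs excluded from the count tables, held-out
#' pairs are scored, and the pooled scores give an AUC (rank statistic)
#' plus a per-fold summary.
#'
#' @param gold A [GoldStandard-class].
#' @param evidence An [EvidenceCollection-class].
#' @param nFolds Number of folds (>= 2; both classes must populate every
#'   fold).
#' @param nBins,alpha Discretisation and smoothing (see
#'   [trainNaiveBayes()]).
#' @param seed Integer RNG seed for the fold assignment.
#' @return list with `auc`, `scores` (data.frame `pair`, `label`,
#'   `logPosteriorOdds`, `fold`) and `folds`.
#' @export
crossValidateNetwork <- function(gold, evidence, nFolds = 5, nBins = 5,
                                 alpha = 1, seed = 1) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  pos <- positivePairs(gold); neg <- negativePairs(gold)
  if (length(pos) < nFolds || length(neg) < nFolds)
    stop("each class needs at least nFolds pairs")
  binned <- binEvidence(evidence, nBins)
  set.seed(as.integer(seed))
  assignFolds <- function() {
    c(setNames(sample(rep(seq_len(nFolds), length.out = length(pos))), pos),
      setNames(sample(rep(seq_len(nFolds), length.out = length(neg))), neg))
  }
  folds <- assignFolds()
  degenerate <- function(f) any(vapply(seq_len(nFolds), function(k)
    !any(f[pos] == k) || !any(f[neg] == k), TRUE))
  if (degenerate(folds)) folds <- assignFolds()
  if (degenerate(folds)) stop("degenerate fold assignment")
  rows <- list()
  for (k in seq_len(nFolds)) {
    heldPos <- pos[folds[pos] == k]; heldNeg <- neg[folds[neg] == k]
    trainGold <- new("GoldStandard",
                     positives = setdiff(pos, heldPos),
                     negatives = setdiff(neg, heldNeg),
                     contextGenes = goldContextGenes(gold))
    model <- suppressWarnings(trainNaiveBayes(trainGold, binned, alpha))
    held <- c(heldPos, heldNeg)
    net <- scorePairs(model, binned, held)
    e <- networkEdges(net)
    lo <- setNames(log(e$posteriorOdds), pairKey(e$geneA, e$geneB))
    rows[[k]] <- data.frame(pair = held,
                            label = c(rep(1L, length(heldPos)),
                                      rep(0L, length(heldNeg))),
                            logPosteriorOdds = as.numeric(lo[held]),
                            fold = k, stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  r <- rank(scores$logPosteriorOdds)
  nP <- sum(scores$label == 1); nN <- sum(scores$label == 0)
  auc <- (sum(r[scores$label == 1]) - nP * (nP + 1) / 2) / (nP * nN)
  list(auc = auc, scores = scores, folds = folds)
}

#' Hypergeometric DE-recapitulation test of a gene neighborhood
#'
#' One-sided hypergeometric tail probability of observing at least the
#' seen overlap between a network neighborhood and the differentially
#' expressed genes (`fdr < fdrCut`), with the tested genes as the
#' universe. Neighbors outside the tested universe are reported and
#' dropped.
#'
#' @param neighbors Character vector of neighborhood genes (non-empty).
#' @param de DE data.frame from [nbExactTest()].
#' @param fdrCut FDR cutoff (default 0.1).
#' @return list with `pvalue`, `overlap`, `nNeighbors`, `nDE`,
#'   `nUniverse`, `dropped`.
#' @export
deRecapitulation <- function(neighbors, de, fdrCut = 0.1) {
  neighbors <- unique(neighbors)
  if (!length(neighbors)) stop("neighbor list is empty")
  universe <- de$gene
  dropped <- setdiff(neighbors, universe)
  if (length(dropped))
    message(length(dropped), " neighbor(s) outside the tested universe dropped")
  neighbors <- intersect(neighbors, universe)
  if (!length(neighbors)) stop("no neighbors left inside the tested universe")
  deGenes <- de$gene[de$fdr < fdrCut]
  overlap <- length(intersect(neighbors, deGenes))
  p <- phyper(overlap - 1, length(deGenes),
              length(universe) - length(deGenes), length(neighbors),
              lower.tail = FALSE)
  list(pvalue = p, overlap = overlap, nNeighbors = length(neighbors),
       nDE = length(deGenes), nUniverse = length(universe),
       dropped = dropped)
}

#' Map a network into another gene namespace via an ortholog table
#'
#' Edges with both endpoints mapped are renamed (and re-canonicalised);
#' edges with an unmapped endpoint are dropped, with the count recorded
#' in the result's metadata (`nDropped`). The map must be injective in
#' both columns.
#'
#' @param net A [FunctionalNetwork-class].
#' @param map data.frame with columns `from`, `to`.
#' @return A [FunctionalNetwork-class] in the target namespace.
#' @export
mapOrthologs <- function(net, map) {
  if (anyDuplicated(map$from) || anyDuplicated(map$to)) {
    bad <- unique(c(map$from[duplicated(map$from)],
                    map$to[duplicated(map$to)]))
    stop("ortholog map is not injective; colliding ids: ",
         paste(head(bad, 5), collapse = ", "))
  }
  e <- networkEdges(net)
  to <- setNames(as.character(map$to), as.character(map$from))
  a <- to[e$geneA]; b <- to[e$geneB]
  keep <- !is.na(a) & !is.na(b)
  mapped <- data.frame(geneA = a[keep], geneB = b[keep],
                       posteriorOdds = e$posteriorOdds[keep],
                       foldOverPrior = e$foldOverPrior[keep],
                       stringsAsFactors = FALSE)
  md <- net@metadata
  md$nDropped <- sum(!keep)
  FunctionalNetwork(mapped, priorOdds = net@priorOdds, metadata = md)
}
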