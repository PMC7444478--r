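# Shared fixtures and independent brute-force oracles used across the
# suite. Oracles are deliberately naive re-statements of the definitions.

smallSim <- function(seed = 1, nGenes = 300, reps = 3, ...) {
  simulateCounts(nGenes, makeDesign(reps),
                 simulationParams(nSignature = 30, ...), seed = seed)
}

# fully exchangeable null: no stage and no genotype structure
nullSim <- function(seed = 1, nGenes = 200, reps = 3, ...) {
  simulateCounts(nGenes, makeDesign(reps),
                 simulationParams(deFraction = 0, stageEffectFraction = 0,
                                  nSignature = 20, ...), seed = seed)
}

# step-up BH definition, evaluated literally
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m] * m / (i:m), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# all-pairs Euclidean distance by explicit loops
bruteDist <- function(expr) {
  n <- ncol(expr)
  d <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((expr[, i] - expr[, j])^2))
  d
}

# mean cross-genotype distance contrast by explicit loops
bruteSepStat <- function(expr, design, focal, reference) {
  md <- function(st) {
    w <- design$sample_id[design$stage == st & design$genotype == "WT"]
    k <- design$sample_id[design$stage == st & design$genotype == "KI"]
    tot <- 0
    for (i in w) for (j in k)
      tot <- tot + sqrt(sum((expr[, i] - expr[, j])^2))
    tot / (length(w) * length(k))
  }
  md(focal) - md(reference)
}

# PAGE z from the definition, scalar arithmetic only
brutePage <- function(scores, members) {
  mu <- sum(scores) / length(scores)
  delta <- sqrt(sum((scores - mu)^2) / length(scores))
  members <- members[members %in% names(scores)]
  m <- length(members)
  sm <- sum(scores[members]) / m
  (sm - mu) * sqrt(m) / delta
}

# hypergeometric upper tail by direct summation of the mass function
bruteHyperTail <- function(overlap, nDE, nUniverse, nNeighbors) {
  ks <- overlap:min(nDE, nNeighbors)
  sum(choose(nDE, ks) * choose(nUniverse - nDE, nNeighbors - ks)) /
    choose(nUniverse, nNeighbors)
}

# breadth-first search truncated at a depth, independent of igraph
bruteBFS <- function(edges, from, maxDepth) {
  adj <- list()
  addE <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (r in seq_len(nrow(edges))) {
    addE(edges$geneA[r], edges$geneB[r])
    addE(edges$geneB[r], edges$geneA[r])
  }
  depth <- setNames(0L, from)
  frontier <- from
  for (d in seq_len(maxDepth)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), names(depth))
    if (!length(nxt)) break
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

# toy 10-pair gold standard + single evidence dataset with a known
# high-bin likelihood ratio of 4 (P(high|pos)=0.8, P(high|neg)=0.2
# before smoothing)
toyNetworkFixture <- function() {
  genes <- sprintf("t%02d", 1:12)
  pos <- pairKey(genes[c(1, 1, 2, 2, 3)], genes[c(2, 3, 3, 4, 4)])
  neg <- pairKey(genes[c(5, 5, 6, 7, 8)], genes[c(6, 7, 8, 9, 10)])
  # scores: high bin = score 1, low bin = score 0
  highPos <- pos[1:4]; lowPos <- pos[5]
  highNeg <- neg[1]; lowNeg <- neg[2:5]
  keys <- c(highPos, lowPos, highNeg, lowNeg)
  ab <- splitPairKey(keys)
  d <- data.frame(geneA = ab[, 1], geneB = ab[, 2],
                  score = c(rep(1, 4), 0, 1, rep(0, 4)))
  list(gold = new("GoldStandard", positives = pos, negatives = neg,
                  contextGenes = genes),
       evidence = EvidenceCollection(list(toy = d)),
       pos = pos, neg = neg, genes = genes)
}
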