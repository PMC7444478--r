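test_that("context genes follow the strict CPM rules", {
  g <- sprintf("g%02d", 1:6)
  rud <- matrix(c(60, 50, 100, 5, 80, 40), 6, 2,
                dimnames = list(g, c("r1", "r2")))
  rud[, 2] <- rud[, 1]
  adu <- matrix(c(5, 5, 10, 5, 20, 5), 6, 2,
                dimnames = list(g, c("a1", "a2")))
  adu[, 2] <- adu[, 1]
  ctx <- contextGenes(rud, adu, highCut = 50, lowCut = 10)
  # g01: 60 > 50 & 5 < 10 -> in; g02: 50 not > 50 -> out (strict);
  # g03: adult 10 not < 10 -> out; g05: adult 20 -> out; g06: 40 -> out
  expect_identical(ctx, "g01")
  withSets <- contextGenes(rud, adu, comparativeSets = list(c("g06", "zz")))
  expect_setequal(withSets, c("g01", "g06", "zz"))

  set.seed(31)
  for (i in 1:20) {
    r <- matrix(runif(40 * 3, 0, 120), 40, 3,
                dimnames = list(sprintf("x%02d", 1:40), NULL))
    a <- matrix(runif(40 * 3, 0, 40), 40, 3, dimnames = dimnames(r))
    oracle <- sort(rownames(r)[rowMeans(r) > 50 & rowMeans(a) < 10])
    expect_identical(contextGenes(r, a), oracle)
  }
})

test_that("gold standards apply the positive and negative rules", {
  genes <- sprintf("g%02d", 1:10)
  context <- genes[1:6]
  known <- pairKey(c("g01", "g01", "g02", "g07"),
                   c("g02", "g03", "g07", "g08"))
  universe <- c(known, pairKey(c("g04", "g05", "g09"),
                               c("g05", "g09", "g10")))
  gs <- buildGoldStandard(context, known, universe,
                          negativesPerPositive = 1, seed = 1)
  # positives: both members inside context
  expect_setequal(positivePairs(gs), pairKey(c("g01", "g01"), c("g02", "g03")))
  # a known pair with one member failing the rule is negative-eligible
  expect_true(pairKey("g02", "g07") %in%
                setdiff(universe, positivePairs(gs)))
  expect_equal(length(negativePairs(gs)), 2)  # ratio 1:1
  expect_length(intersect(positivePairs(gs), negativePairs(gs)), 0)

  # saturation: everything known and in context leaves no negatives
  ctxAll <- genes
  cb <- combn(genes, 2)
  knownAll <- pairKey(cb[1, ], cb[2, ])
  allPairs <- knownAll
  expect_error(buildGoldStandard(ctxAll, allPairs, allPairs, 1), "negative")

  expect_error(buildGoldStandard(c("zz1", "zz2"), known, universe, 1),
               "no positive")
})

test_that("gold-standard class balance matches the configuration", {
  sim <- smallSim(seed = 32, nGenes = 150)
  ev <- simulateEvidence(sim$truth, 2, 0.8, 0.5, seed = 33,
                         betweenPerWithin = 8)
  known <- simulateKnownInteractions(sim$truth, 0.3, seed = 34)
  gs <- buildGoldStandard(geneUniverse(sim$truth), known,
                          pairUniverse(ev), negativesPerPositive = 5,
                          seed = 35)
  expect_equal(length(negativePairs(gs)),
               round(5 * length(positivePairs(gs))))
})

test_that("evidence binning is quantile-balanced with a missing bin", {
  sc <- 1:100
  ab <- t(combn(sprintf("e%03d", 1:15), 2))[1:100, ]
  ev <- EvidenceCollection(list(d1 = data.frame(geneA = ab[, 1],
                                                geneB = ab[, 2],
                                                score = sc)))
  b2 <- binEvidence(ev, nBins = 2)
  tab <- table(b2@bins$d1)
  expect_equal(unname(tab[["1"]]), 50)
  expect_equal(unname(tab[["2"]]), 50)

  # a pair never scored maps to the missing bin
  expect_equal(microdevnet:::.pairBins(b2, "d1", pairKey("zz1", "zz2")), 3L)

  set.seed(36)
  ev2 <- EvidenceCollection(list(d = data.frame(geneA = ab[, 1],
                                                geneB = ab[, 2],
                                                score = rnorm(100))))
  for (nb in c(2, 4, 5)) {
    occ <- table(binEvidence(ev2, nb)@bins$d)
    expect_lte(max(occ) - min(occ), 1)
  }

  const <- EvidenceCollection(list(d = data.frame(geneA = ab[, 1],
                                                  geneB = ab[, 2],
                                                  score = 1)))
  expect_warning(bc <- binEvidence(const, 3), "constant")
  expect_true(all(bc@bins$d == 1L))
  expect_error(binEvidence(ev, 1), "nBins")
})

test_that("training recovers hand-counted likelihood ratios", {
  fx <- toyNetworkFixture()
  binned <- binEvidence(fx$evidence, nBins = 2)
  m <- trainNaiveBayes(fx$gold, binned, alpha = 1e-9)
  tb <- m@tables$toy
  # P(high|pos) = 4/5, P(high|neg) = 1/5: likelihood ratio 4
  expect_equal(tb["pos", 2] / tb["neg", 2], 4, tolerance = 1e-6)
  expect_equal(m@priorOdds, 1)

  # heavy smoothing drives every ratio to 1
  mFlat <- trainNaiveBayes(fx$gold, binned, alpha = 1e9)
  expect_equal(unname(mFlat@tables$toy["pos", ] / mFlat@tables$toy["neg", ]),
               rep(1, 3), tolerance = 1e-6)

  # bit-identical retraining
  expect_identical(trainNaiveBayes(fx$gold, binned, 1),
                   trainNaiveBayes(fx$gold, binned, 1))

  # a dataset with no gold coverage is dropped
  other <- EvidenceCollection(list(
    far = data.frame(geneA = "q01", geneB = "q02", score = 1)))
  b2 <- binEvidence(other, 2)
  expect_warning(m2 <- trainNaiveBayes(fx$gold, b2, 1), "dropped")
  expect_length(m2@tables, 0)
})

test_that("pair scoring multiplies likelihood ratios onto the prior", {
  fx <- toyNetworkFixture()
  binned <- binEvidence(fx$evidence, nBins = 2)
  # constructed model: prior odds 0.1, high-bin ratio 4
  model <- new("NaiveBayesModel", priorOdds = 0.1,
               tables = list(toy = rbind(pos = c(0.19, 0.8, 0.01),
                                         neg = c(0.79, 0.2, 0.01))),
               binEdges = binned@binEdges, nBins = 2L, alpha = 1)
  highPair <- fx$pos[1]  # scored 1 -> high bin
  net <- scorePairs(model, binned, highPair)
  e <- networkEdges(net)
  expect_equal(e$posteriorOdds, 0.4, tolerance = 1e-12)
  expect_equal(e$foldOverPrior, 4, tolerance = 1e-12)

  # zero datasets: posterior = prior for every pair
  empty <- new("NaiveBayesModel", priorOdds = 0.25, tables = list(),
               binEdges = list(), nBins = 2L, alpha = 1)
  netE <- scorePairs(empty, binned, fx$pos)
  expect_true(all(networkEdges(netE)$posteriorOdds == 0.25))

  # log-additivity against independent summation over datasets
  sim <- smallSim(seed = 37, nGenes = 150)
  ev <- simulateEvidence(sim$truth, 4, 0.8, 0.5, seed = 38)
  known <- simulateKnownInteractions(sim$truth, 0.4, seed = 39)
  gold <- buildGoldStandard(geneUniverse(sim$truth), known,
                            pairUniverse(ev), 3, seed = 40)
  bn <- binEvidence(ev, 5)
  mod <- trainNaiveBayes(gold, bn, 1)
  set.seed(99)
  pairs <- sample(pairUniverse(ev), 200)
  net2 <- scorePairs(mod, bn, pairs)
  e2 <- networkEdges(net2)
  key2 <- pairKey(e2$geneA, e2$geneB)
  for (i in seq_len(20)) {
    k <- key2[i]
    s <- log(mod@priorOdds)
    for (nm in names(mod@tables)) {
      b <- microdevnet:::.pairBins(bn, nm, k)
      s <- s + log(mod@tables[[nm]]["pos", b]) -
        log(mod@tables[[nm]]["neg", b])
    }
    expect_equal(log(e2$posteriorOdds[i]), s, tolerance = 1e-10)
  }
})

test_that("thresholding is inclusive and monotone", {
  edges <- data.frame(geneA = c("a", "a", "b"), geneB = c("b", "c", "c"),
                      posteriorOdds = c(0.5, 0.4, 0.39))
  net <- FunctionalNetwork(edges, priorOdds = 0.1)
  th5 <- thresholdNetwork(net, 5)
  # 0.5/0.1 = 5.0 retained (inclusive); folds 4 and 3.9 removed
  expect_setequal(pairKey(networkEdges(th5)$geneA, networkEdges(th5)$geneB),
                  "a|b")
  expect_true(all(networkEdges(th5)$foldOverPrior >= 5))
  for (cut in c(1, 2, 4, 5, 6)) {
    lo <- nrow(networkEdges(thresholdNetwork(net, cut)))
    hi <- nrow(networkEdges(thresholdNetwork(net, cut + 0.5)))
    expect_lte(hi, lo)
  }
})

test_that("top neighbors are ranked, tie-broken and truncated", {
  edges <- data.frame(geneA = c("s", "s", "s", "a"),
                      geneB = c("a", "b", "c", "b"),
                      posteriorOdds = c(3, 5, 3, 9))
  net <- FunctionalNetwork(edges, priorOdds = 0.5)
  nb <- topNeighbors(net, "s", k = 25)
  expect_equal(nb$gene, c("b", "a", "c"))  # tie at 3 broken a < c
  expect_equal(nrow(topNeighbors(net, "s", k = 2)), 2)
  expect_error(topNeighbors(net, "zz", 5), "not in the network")
})

test_that("module co-members dominate a seed gene's neighborhood", {
  recov <- vapply(1:5, function(s) {
    sim <- simulateCounts(120, makeDesign(2),
                          simulationParams(nSignature = 12, moduleSize = 10),
                          seed = 700 + s)
    ev <- simulateEvidence(sim$truth, 10, 0.8, 0.5, seed = 800 + s)
    known <- simulateKnownInteractions(sim$truth, 0.5, seed = 900 + s)
    gold <- buildGoldStandard(geneUniverse(sim$truth), known,
                              pairUniverse(ev), 5, seed = 1000 + s)
    bn <- binEvidence(ev, 5)
    mod <- trainNaiveBayes(gold, bn, 1)
    net <- scorePairs(mod, bn, pairUniverse(ev))
    mods <- sim$truth@modules
    seedGene <- names(mods)[mods == 1][1]
    mates <- setdiff(names(mods)[mods == mods[seedGene]], seedGene)
    nb <- topNeighbors(net, seedGene, k = length(mates))
    mean(mates %in% nb$gene)
  }, numeric(1))
  expect_gte(mean(recov >= 0.8), 0.8)
})

test_that("TF linking equals truncated breadth-first search", {
  edges <- data.frame(geneA = c("n1", "x", "n2", "y", "tf1"),
                      geneB = c("x", "tf1", "y", "z", "n3"),
                      posteriorOdds = rep(10, 5))
  net <- FunctionalNetwork(edges, priorOdds = 0.5)
  links <- linkTFs(net, c("n1", "n2", "n3"), c("tf1", "tf9"), maxSteps = 2)
  # n3 adjacent (1 step), n1 via x (2 steps), n2 too far (3 steps)
  expect_setequal(links$tf1$gene, c("n1", "n3"))
  expect_equal(links$tf1$steps[links$tf1$gene == "n3"], 1L)
  expect_equal(links$tf1$steps[links$tf1$gene == "n1"], 2L)
  expect_equal(nrow(links$tf9), 0)  # absent TF: unreachable, no error

  set.seed(41)
  for (i in 1:50) {
    g <- sprintf("v%02d", 1:15)
    ab <- t(combn(g, 2))
    pick <- sample(nrow(ab), 25)
    e <- data.frame(geneA = ab[pick, 1], geneB = ab[pick, 2],
                    posteriorOdds = 10)
    nw <- FunctionalNetwork(e, priorOdds = 0.5)
    tf <- sample(g, 1)
    nbh <- sample(setdiff(g, tf), 6)
    got <- linkTFs(nw, nbh, tf, maxSteps = 2)[[tf]]
    depth <- bruteBFS(networkEdges(nw), tf, 2)
    want <- sort(intersect(nbh, names(depth)[depth >= 1 & depth <= 2]))
    expect_identical(sort(got$gene), want)
    if (nrow(got))
      expect_identical(setNames(got$steps, got$gene)[want],
                       setNames(as.integer(depth[want]), want))
  }
})

test_that("cross-validation calibrates to chance and to clean signal", {
  sim <- smallSim(seed = 42, nGenes = 200)
  # label-independent evidence: AUC near 0.5
  evNull <- simulateEvidence(sim$truth, 5, 1e-6, 1, seed = 43,
                             betweenPerWithin = 6)
  known <- simulateKnownInteractions(sim$truth, 0.7, seed = 44)
  goldN <- buildGoldStandard(geneUniverse(sim$truth), known,
                             pairUniverse(evNull), 3, seed = 45)
  cvN <- crossValidateNetwork(goldN, evNull, 5, seed = 46)
  expect_lt(abs(cvN$auc - 0.5), 0.05)

  # effectively noise-free planted evidence: AUC >= 0.95
  evS <- simulateEvidence(sim$truth, 5, 1, 0.05, seed = 47,
                          betweenPerWithin = 6)
  goldS <- buildGoldStandard(geneUniverse(sim$truth), known,
                             pairUniverse(evS), 3, seed = 48)
  cvS <- crossValidateNetwork(goldS, evS, 5, seed = 49)
  expect_gte(cvS$auc, 0.95)

  # reproducible folds
  cv2 <- crossValidateNetwork(goldS, evS, 5, seed = 49)
  expect_identical(cvS$folds, cv2$folds)
  expect_equal(cvS$auc, cv2$auc)
})

test_that("DE recapitulation equals hypergeometric tail summation", {
  de <- data.frame(gene = sprintf("g%03d", 1:100), log2fc = 0,
                   pvalue = 1, fdr = c(rep(0.01, 20), rep(0.9, 80)),
                   stage = "brain_rudiment")
  # neighbors = exactly the DE genes: minimal achievable p
  rAll <- deRecapitulation(de$gene[1:20], de, 0.1)
  expect_equal(rAll$overlap, 20)
  expect_equal(rAll$pvalue, bruteHyperTail(20, 20, 100, 20),
               tolerance = 1e-12)
  # zero overlap: tail at >= 0 is 1
  rNone <- deRecapitulation(de$gene[21:30], de, 0.1)
  expect_equal(rNone$overlap, 0)
  expect_equal(rNone$pvalue, 1)

  set.seed(50)
  for (i in 1:50) {
    nDE <- sample(5:30, 1)
    fdr <- rep(0.9, 60); fdr[sample(60, nDE)] <- 0.01
    de2 <- data.frame(gene = sprintf("h%02d", 1:60), log2fc = 0,
                      pvalue = 1, fdr = fdr, stage = "adult")
    nb <- sample(de2$gene, sample(3:20, 1))
    r <- deRecapitulation(nb, de2, 0.1)
    expect_equal(r$pvalue,
                 bruteHyperTail(r$overlap, nDE, 60, length(nb)),
                 tolerance = 1e-10)
  }
  expect_error(deRecapitulation(character(0), de), "empty")
  expect_message(deRecapitulation(c(de$gene[1:5], "outside"), de, 0.1),
                 "dropped")
})

test_that("ortholog mapping renames, drops and rejects collisions", {
  edges <- data.frame(geneA = c("a", "a", "b"), geneB = c("b", "c", "d"),
                      posteriorOdds = c(2, 3, 4))
  net <- FunctionalNetwork(edges, priorOdds = 0.5)

  idMap <- data.frame(from = c("a", "b", "c", "d"),
                      to = c("a", "b", "c", "d"))
  same <- mapOrthologs(net, idMap)
  expect_equal(networkEdges(same)[, c("geneA", "geneB", "posteriorOdds")],
               networkEdges(net)[, c("geneA", "geneB", "posteriorOdds")])
  expect_equal(same@metadata$nDropped, 0)

  partial <- data.frame(from = c("a", "b"), to = c("A", "B"))
  mapped <- mapOrthologs(net, partial)
  expect_equal(nrow(networkEdges(mapped)), 1)  # only a-b fully mapped
  expect_equal(mapped@metadata$nDropped, 2)
  expect_setequal(c(networkEdges(mapped)$geneA, networkEdges(mapped)$geneB),
                  c("A", "B"))

  clash <- data.frame(from = c("a", "b"), to = c("X", "X"))
  expect_error(mapOrthologs(net, clash), "injective")

  set.seed(51)
  for (i in 1:20) {
    g <- sprintf("m%02d", 1:12)
    ab <- t(combn(g, 2)); pick <- sample(nrow(ab), 20)
    e <- data.frame(geneA = ab[pick, 1], geneB = ab[pick, 2],
                    posteriorOdds = runif(20, 1, 10))
    nw <- FunctionalNetwork(e, priorOdds = 0.2)
    sub <- sample(g, 7)
    mp <- data.frame(from = sub, to = toupper(sub))
    got <- mapOrthologs(nw, mp)
    keep <- e$geneA %in% sub & e$geneB %in% sub
    expect_equal(nrow(networkEdges(got)), sum(keep))
    expect_equal(got@metadata$nDropped, sum(!keep))
  }
})
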