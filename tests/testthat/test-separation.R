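test_that("euclideanDistances matches a double-loop oracle", {
  e <- matrix(c(1, 4), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(as.matrix(euclideanDistances(e))["s1", "s2"], 3)

  dup <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  dup <- cbind(dup, b2 = dup[, "b"])
  expect_equal(as.matrix(euclideanDistances(dup))["b", "b2"], 0)

  set.seed(11)
  for (i in 1:50) {
    m <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(sprintf("g%02d", 1:50), letters[1:8]))
    expect_equal(as.matrix(euclideanDistances(m)), bruteDist(m),
                 tolerance = 1e-10)
  }
  bad <- matrix(c(1, NA), 1, 2, dimnames = list("g", c("x", "y")))
  expect_error(euclideanDistances(bad), "finite")
})

test_that("classical MDS reconstructs Euclidean geometry", {
  # 3 collinear points, distances 1, 1, 2: one positive eigenvalue
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  r <- classicalMDS(as.dist(d), k = 2)
  expect_equal(sum(r$eig > 1e-10), 1)
  expect_true(all(abs(r$eig[-which.max(r$eig)]) <= 1e-10))

  set.seed(12)
  for (i in 1:10) {
    pts <- matrix(rnorm(7 * 4), 7, 4)
    rownames(pts) <- letters[1:7]
    d <- dist(pts)
    emb <- classicalMDS(d, k = 6)
    expect_equal(as.matrix(dist(emb$points)), as.matrix(d),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # ordering invariance up to rigid motion: distances survive reshuffling
    perm <- sample(7)
    emb2 <- classicalMDS(as.dist(as.matrix(d)[perm, perm]), k = 6)
    expect_equal(as.matrix(dist(emb2$points)),
                 as.matrix(d)[perm, perm], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }

  nonEuc <- matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3, 3)  # triangle violation
  expect_warning(classicalMDS(as.dist(nonEuc), 2), "not Euclidean")
  expect_error(classicalMDS(d, k = 10), "k must be")
})

test_that("the separation statistic obeys its algebraic identities", {
  design <- makeDesign(3)
  g <- sprintf("g%02d", 1:40)
  set.seed(13)
  expr <- matrix(rnorm(40 * nrow(design)), 40, nrow(design),
                 dimnames = list(g, design$sample_id))

  flat <- matrix(5, 40, nrow(design), dimnames = dimnames(expr))
  expect_equal(separationStatistic(flat, design, "brain_rudiment",
                                   "yolk_sac"), 0)

  s1 <- separationStatistic(expr, design, "brain_rudiment", "adult")
  s2 <- separationStatistic(expr, design, "adult", "brain_rudiment")
  expect_equal(s1, -s2)

  for (i in 1:50) {
    e <- matrix(rnorm(40 * nrow(design)), 40, nrow(design),
                dimnames = dimnames(expr))
    expect_equal(separationStatistic(e, design, "brain_rudiment", "neonate"),
                 bruteSepStat(e, design, "brain_rudiment", "neonate"),
                 tolerance = 1e-10)
  }

  # relabeling samples within a (stage, genotype) cell leaves it unchanged
  d2 <- design
  i1 <- which(d2$stage == "brain_rudiment" & d2$genotype == "KI")[1:2]
  d2$sample_id[i1] <- d2$sample_id[rev(i1)]
  expect_equal(separationStatistic(expr, d2, "brain_rudiment", "yolk_sac"),
               separationStatistic(expr, design, "brain_rudiment",
                                   "yolk_sac"))

  d3 <- design[!(design$stage == "adult" & design$genotype == "KI"), ]
  expect_error(separationStatistic(expr[, d3$sample_id], d3,
                                   "brain_rudiment", "adult"), "missing")
})

test_that("permutation p-values respect the Phipson-Smyth bounds", {
  sim <- smallSim(seed = 14, nGenes = 150)
  v <- vst(sim$experiment)
  design <- sampleDesign(sim$experiment)
  res <- permutationTest(v, design, "brain_rudiment", "yolk_sac",
                         nPerm = 1000, seed = 15)
  expect_equal(res@pvalue, (res@b + 1) / 1001)
  expect_gte(res@pvalue, 1 / 1001)
  expect_lte(res@pvalue, 1)
  # strong planted effect: the floor is attained
  expect_equal(res@b, 0L)
  expect_equal(res@pvalue, 1 / 1001)

  # determinism and seed sensitivity
  res2 <- permutationTest(v, design, "brain_rudiment", "yolk_sac",
                          nPerm = 200, seed = 16)
  res3 <- permutationTest(v, design, "brain_rudiment", "yolk_sac",
                          nPerm = 200, seed = 16)
  expect_identical(res2@b, res3@b)

  # an observed statistic below every permutation value gives p = 1:
  # reverse the contrast so the observed value is strongly negative
  resR <- permutationTest(v, design, "yolk_sac", "brain_rudiment",
                          nPerm = 500, seed = 17)
  expect_equal(resR@b, 500L)
  expect_equal(resR@pvalue, 1)
})

test_that("power increases with the planted effect size", {
  med <- vapply(c(0, 0.5, 1, 2), function(fc) {
    pv <- vapply(1:20, function(s) {
      sim <- simulateCounts(150, makeDesign(3),
                            simulationParams(deLog2FC = fc,
                                             stageEffectFraction = 0,
                                             nSignature = 15),
                            seed = 1000 * fc + s)
      v <- vst(sim$experiment)
      permutationTest(v, sampleDesign(sim$experiment), "brain_rudiment",
                      "yolk_sac", nPerm = 99, seed = s)@pvalue
    }, numeric(1))
    median(pv)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("subsampling reduces to the full test when all genes are kept", {
  sim <- smallSim(seed = 18, nGenes = 120)
  v <- vst(sim$experiment)
  design <- sampleDesign(sim$experiment)
  sub <- subsampleRobustness(v, design, "brain_rudiment", "yolk_sac",
                             nGenes = nrow(v), nReps = 3, nPerm = 99,
                             seed = 19)
  for (r in 1:3) {
    full <- permutationTest(v, design, "brain_rudiment", "yolk_sac",
                            nPerm = 99,
                            seed = microdevnet:::.childSeed(19, 2L * r))
    expect_identical(sub$pvalues[r], full@pvalue)
  }
  expect_error(subsampleRobustness(v, design, "brain_rudiment", "yolk_sac",
                                   nGenes = nrow(v) + 1), "exceeds")
})

test_that("subsampled tests stay significant under a strong effect", {
  sim <- simulateCounts(1000, makeDesign(3),
                        simulationParams(nSignature = 100), seed = 20)
  v <- vst(sim$experiment)
  sub <- subsampleRobustness(v, sampleDesign(sim$experiment),
                             "brain_rudiment", "yolk_sac",
                             nGenes = 250, nReps = 20, nPerm = 199,
                             seed = 21)
  expect_true(all(sub$pvalues <= 0.01))
})

test_that("the signature test restricts and reduces correctly", {
  sim <- smallSim(seed = 22, nGenes = 120)
  v <- vst(sim$experiment)
  design <- sampleDesign(sim$experiment)
  full <- permutationTest(v, design, "brain_rudiment", "yolk_sac",
                          nPerm = 99, seed = 23)
  same <- signatureTest(v, design, rownames(v), "brain_rudiment",
                        "yolk_sac", nPerm = 99, seed = 23)
  expect_identical(full@b, same@b)
  expect_identical(full@observed, same@observed)
  expect_error(signatureTest(v, design, c("nope1", "nope2"),
                             "brain_rudiment", "yolk_sac"), "intersect")
})

test_that("a planted signature separates better than a null gene set", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulateCounts(300, makeDesign(3),
                          simulationParams(nSignature = 30,
                                           signatureDEFraction = 1),
                          seed = 600 + s)
    v <- vst(sim$experiment)
    design <- sampleDesign(sim$experiment)
    sig <- sim$truth@signatureGenes
    nullSet <- sample(setdiff(rownames(v), names(sim$truth@deGenes$brain_rudiment)),
                      length(sig))
    pSig <- signatureTest(v, design, sig, "brain_rudiment", "yolk_sac",
                          nPerm = 99, seed = s)@pvalue
    pNull <- signatureTest(v, design, nullSet, "brain_rudiment", "yolk_sac",
                           nPerm = 99, seed = s)@pvalue
    if (pSig < pNull) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("signature PCA explains variance as expected", {
  g <- sprintf("g%02d", 1:20)
  base <- rnorm(20)
  rank1 <- outer(base, c(1, 2, 3, 4, 5))
  rownames(rank1) <- g; colnames(rank1) <- sprintf("s%d", 1:5)
  r <- signaturePCA(rank1, g, k = 2)
  expect_equal(r$explained[1], 1)

  set.seed(24)
  expr <- matrix(rnorm(20 * 6), 20, 6,
                 dimnames = list(g, sprintf("s%d", 1:6)))
  sig <- g[1:10]
  full <- signaturePCA(expr, sig, k = 5)
  expect_equal(as.matrix(dist(full$scores)),
               as.matrix(dist(t(expr[sig, ]))), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(signaturePCA(expr, g[1:2], k = 5), "k exceeds")
})
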