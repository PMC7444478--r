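## End-to-end driver: simulate (or load) inputs, run DE, enrichment,
## separation tests and the functional network, and write a run
## directory of TSV artifacts plus a machine-readable summary.

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: 1000
#' permutations, 5000x100 gene subsampling, 10-500 set-size filter, GO
#' FDR 0.01, TF-target FDR 0.1, five-fold-over-prior edge cutoff,
#' top-25 neighborhood, 2-step TF linking, CPM context cuts 50/10, and
#' one master seed from which every stage derives its own child stream.
#'
#' @param seed Master seed.
#' @param nGenes,nReplicates Simulation size.
#' @param simulationParams See [simulationParams()].
#' @param ... Named overrides of nested defaults (replaced wholesale).
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(seed = 1, nGenes = 2000, nReplicates = 4,
                           simulationParams = NULL, ...) {
  cfg <- list(
    seed = seed,
    simulate = list(enabled = TRUE, nGenes = nGenes,
                    nReplicates = nReplicates,
                    params = simulationParams,
                    nGoLike = 50, setSizeRange = c(10, 500),
                    nDatasets = 10,
                    withinModuleSignal = 0.8, noiseSD = 0.5,
                    betweenPerWithin = 4, knownCoverage = 0.2),
    de = list(fdrCut = 0.1, minCPM = 1, minSamples = 2),
    enrichment = list(sizeMin = 10, sizeMax = 500, goFDR = 0.01,
                      tfFDR = 0.1),
    separation = list(nPerm = 1000, focal = "brain_rudiment",
                      references = c("yolk_sac", "neonate", "adult"),
                      subsample = list(enabled = FALSE, nGenes = 5000,
                                       nReps = 100)),
    network = list(highCut = 50, lowCut = 10, negativesPerPositive = 19,
                   nBins = 5, alpha = 1, minFoldOverPrior = 5,
                   topK = 25, maxSteps = 2, nFolds = 5,
                   seedGene = NULL)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param file File path.
#' @return `readPipelineConfig` returns the configuration list.
#' @export
readPipelineConfig <- function(file) yaml::read_yaml(file)

#' @rdname readPipelineConfig
#' @param config Configuration list.
#' @export
writePipelineConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

.stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

.runStage <- function(stage, fn) {
  tryCatch(fn(), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: simulation of counts / gene sets /
#' evidence (stage `simulate`), per-stage differential expression
#' (`de`), PAGE enrichment and TF-target statistics (`enrichment`), the
#' permutation separation tests, MDS and signature PCA (`separation`),
#' and the functional-network build, queries and evaluation
#' (`network`). Every output file in `outdir` is named deterministically
#' and `summary.json` lists each statistic with its producing stage and
#' seed; two runs with an identical configuration are byte-identical.
#'
#' @param config Configuration list from [pipelineConfig()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  summary <- list(seed = seed)

  ## --- simulate -----------------------------------------------------
  sim <- .runStage("simulate", function() {
    .stageLog("simulate", "generating inputs")
    params <- config$simulate$params
    if (is.null(params)) params <- simulationParams()
    counts <- simulateCounts(config$simulate$nGenes,
                             makeDesign(config$simulate$nReplicates),
                             params, seed = .childSeed(seed, 1))
    sets <- simulateGeneSets(counts$truth, config$simulate$nGoLike,
                             sizeRange = config$simulate$setSizeRange,
                             seed = .childSeed(seed, 2))
    evidence <- simulateEvidence(counts$truth, config$simulate$nDatasets,
                                 config$simulate$withinModuleSignal,
                                 config$simulate$noiseSD,
                                 seed = .childSeed(seed, 3),
                                 betweenPerWithin =
                                   config$simulate$betweenPerWithin)
    known <- simulateKnownInteractions(counts$truth,
                                       config$simulate$knownCoverage,
                                       seed = .childSeed(seed, 4))
    writeCounts(counts$experiment, file.path(outdir, "counts.tsv"),
                file.path(outdir, "design.tsv"))
    writeGMT(sets, file.path(outdir, "gene_sets.gmt"))
    writeEvidenceDir(evidence, file.path(outdir, "evidence"))
    writeLines(known, file.path(outdir, "known_pairs.txt"))
    list(experiment = counts$experiment, truth = counts$truth,
         sets = sets, evidence = evidence, known = known)
  })
  mge <- sim$experiment
  design <- sampleDesign(mge)

  ## --- differential expression --------------------------------------
  de <- .runStage("de", function() {
    .stageLog("de", "NB exact test per stage")
    de <- deByStage(mge, minCPM = config$de$minCPM,
                    minSamples = config$de$minSamples)
    for (st in names(de))
      .writeTSV(de[[st]], file.path(outdir, sprintf("de_%s.tsv", st)))
    de
  })
  summary$de <- lapply(de, function(d)
    list(nTested = nrow(d), nSignificant = sum(d$fdr < config$de$fdrCut)))

  ## --- enrichment ----------------------------------------------------
  enr <- .runStage("enrichment", function() {
    .stageLog("enrichment", "PAGE and TF-target statistics")
    cats <- setCategory(sim$sets)
    goSets <- GeneSetCollection(geneSets(sim$sets)[cats == "go_like"],
                                "go_like")
    regulons <- GeneSetCollection(geneSets(sim$sets)[cats == "tf_regulon"],
                                  "tf_regulon")
    page <- lapply(de, function(d)
      pageEnrich(d, goSets, config$enrichment$sizeMin,
                 config$enrichment$sizeMax))
    for (st in names(page))
      .writeTSV(page[[st]],
                file.path(outdir, sprintf("enrichment_%s.tsv", st)))
    zmat <- tfZMatrix(de, regulons)
    .writeTSV(data.frame(tf = rownames(zmat), zmat, check.names = FALSE),
              file.path(outdir, "tf_z.tsv"))
    frac <- tfTargetFraction(de, regulons, config$enrichment$tfFDR)
    .writeTSV(frac, file.path(outdir, "tf_fractions.tsv"))
    list(page = page, zmat = zmat, frac = frac)
  })
  summary$enrichment <- lapply(enr$page, function(p) {
    sig <- p[p$fdr <= config$enrichment$goFDR, , drop = FALSE]
    list(nTested = nrow(p), nSignificant = nrow(sig),
         topSet = if (nrow(p)) p$set_name[which.max(abs(p$rank_score))]
                  else NA)
  })

  ## --- separation -----------------------------------------------------
  sep <- .runStage("separation", function() {
    .stageLog("separation", "vst, MDS, permutation tests")
    v <- vst(mge)
    mds <- classicalMDS(euclideanDistances(v), k = 3)
    .writeTSV(data.frame(sample_id = rownames(mds$points), mds$points,
                         check.names = FALSE),
              file.path(outdir, "mds_coordinates.tsv"))
    focal <- config$separation$focal
    tests <- list()
    rows <- list()
    for (i in seq_along(config$separation$references)) {
      ref <- config$separation$references[i]
      res <- permutationTest(v, design, focal, ref,
                             config$separation$nPerm,
                             seed = .childSeed(seed, 10 + i))
      tests[[ref]] <- res
      rows[[ref]] <- data.frame(focal = focal, reference = ref,
                                observed = res@observed, b = res@b,
                                n_perm = res@nPerm, pvalue = res@pvalue,
                                seed = res@seed)
    }
    sig <- signatureTest(v, design, sim$truth@signatureGenes, focal,
                         config$separation$references[1],
                         config$separation$nPerm,
                         seed = .childSeed(seed, 14))
    rows[["signature"]] <- data.frame(focal = focal,
                                      reference = config$separation$references[1],
                                      observed = sig@observed, b = sig@b,
                                      n_perm = sig@nPerm, pvalue = sig@pvalue,
                                      seed = sig@seed)
    .writeTSV(do.call(rbind, rows), file.path(outdir, "separation_tests.tsv"))
    pca <- signaturePCA(v, sim$truth@signatureGenes, k = 3)
    .writeTSV(data.frame(sample_id = rownames(pca$scores), pca$scores,
                         check.names = FALSE),
              file.path(outdir, "signature_pca.tsv"))
    sub <- NULL
    if (isTRUE(config$separation$subsample$enabled)) {
      sub <- subsampleRobustness(v, design, focal,
                                 config$separation$references[1],
                                 config$separation$subsample$nGenes,
                                 config$separation$subsample$nReps,
                                 config$separation$nPerm,
                                 seed = .childSeed(seed, 15))
      .writeTSV(data.frame(replicate = seq_along(sub$pvalues),
                           pvalue = sub$pvalues),
                file.path(outdir, "subsample_pvalues.tsv"))
    }
    list(tests = tests, signature = sig, pca = pca, subsample = sub)
  })
  summary$separation <- list(
    pvalues = lapply(sep$tests, function(t)
      list(pvalue = t@pvalue, observed = t@observed, seed = t@seed)),
    signature = list(pvalue = sep$signature@pvalue,
                     observed = sep$signature@observed,
                     seed = sep$signature@seed),
    pcaExplained = as.numeric(sep$pca$explained))
  if (!is.null(sep$subsample))
    summary$separation$subsampleMedianP <- sep$subsample$median

  ## --- network --------------------------------------------------------
  net <- .runStage("network", function() {
    .stageLog("network", "gold standard, training, queries")
    cp <- cpm(mge)
    rud <- cp[, design$stage == "brain_rudiment", drop = FALSE]
    adu <- cp[, design$stage == "adult", drop = FALSE]
    ## the module universe stands in for the comparative microglia-vs-
    ## other-cell-type gene lists of the context definition
    ctx <- contextGenes(rud, adu, config$network$highCut,
                        config$network$lowCut,
                        comparativeSets = list(geneUniverse(sim$truth)))
    gold <- buildGoldStandard(ctx, sim$known, pairUniverse(sim$evidence),
                              config$network$negativesPerPositive,
                              seed = .childSeed(seed, 20))
    .writeTSV(data.frame(
      pair = c(positivePairs(gold), negativePairs(gold)),
      label = c(rep(1L, length(positivePairs(gold))),
                rep(0L, length(negativePairs(gold))))),
      file.path(outdir, "gold_standard.tsv"))
    binned <- binEvidence(sim$evidence, config$network$nBins)
    model <- trainNaiveBayes(gold, binned, config$network$alpha)
    writeNaiveBayesModel(model, file.path(outdir, "model.json"))
    full <- scorePairs(model, binned, pairUniverse(sim$evidence))
    writeNetwork(full, file.path(outdir, "network.tsv"))
    strong <- thresholdNetwork(full, config$network$minFoldOverPrior)
    writeNetwork(strong, file.path(outdir, "network_thresholded.tsv"))
    seedGene <- config$network$seedGene
    if (is.null(seedGene)) {
      ## default analog of the seed-gene query: the first gene of module 1
      mods <- sim$truth@modules
      seedGene <- sort(names(mods)[mods == 1])[1]
    }
    nb <- topNeighbors(full, seedGene, config$network$topK)
    .writeTSV(nb, file.path(outdir, "neighbors.tsv"))
    tfs <- names(sim$truth@regulons)
    links <- linkTFs(strong, nb$gene, tfs, config$network$maxSteps)
    linkRows <- do.call(rbind, lapply(names(links), function(tf)
      if (nrow(links[[tf]])) cbind(tf = tf, links[[tf]]) else NULL))
    if (is.null(linkRows))
      linkRows <- data.frame(tf = character(), gene = character(),
                             steps = integer(), path = character())
    .writeTSV(linkRows, file.path(outdir, "tf_links.tsv"))
    cv <- crossValidateNetwork(gold, sim$evidence, config$network$nFolds,
                               config$network$nBins, config$network$alpha,
                               seed = .childSeed(seed, 21))
    recap <- deRecapitulation(nb$gene, de[["brain_rudiment"]],
                              config$de$fdrCut)
    list(gold = gold, model = model, strong = strong, seedGene = seedGene,
         neighbors = nb, links = links, cv = cv, recap = recap)
  })
  summary$network <- list(
    nPositives = length(positivePairs(net$gold)),
    nNegatives = length(negativePairs(net$gold)),
    priorOdds = priorOdds(net$model),
    nStrongEdges = nrow(networkEdges(net$strong)),
    seedGene = net$seedGene,
    nNeighbors = nrow(net$neighbors),
    nLinkedTFs = sum(vapply(net$links, nrow, 1L) > 0),
    cvAUC = net$cv$auc,
    deRecapitulationP = net$recap$pvalue,
    deRecapitulationOverlap = net$recap$overlap)

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

.fmtNum <- function(x) formatC(x, digits = 12, format = "g")

#' Render a human-readable report from a completed run directory
#'
#' Tabulates DE counts per stage, top enrichments, separation p-values
#' and the network neighborhood / TF links from `summary.json` and the
#' run's TSV artifacts. Missing sections are marked, not fatal; every
#' number printed is taken verbatim from the summary.
#'
#' @param runDir Run directory produced by [runPipeline()].
#' @param file Output file (default `report.md` inside `runDir`).
#' @return Invisibly, the report path.
#' @export
makeReport <- function(runDir, file = file.path(runDir, "report.md")) {
  sfile <- file.path(runDir, "summary.json")
  if (!file.exists(sfile)) stop("no summary.json in ", runDir)
  s <- jsonlite::read_json(sfile, simplifyVector = FALSE)
  lines <- c("# Pipeline report", "",
             sprintf("Master seed: %s", s$seed), "")
  lines <- c(lines, "## Differential expression", "")
  if (!is.null(s$de)) {
    for (st in names(s$de))
      lines <- c(lines, sprintf("- %s: %d significant of %d tested", st,
                                s$de[[st]]$nSignificant, s$de[[st]]$nTested))
  } else lines <- c(lines, "[missing: differential expression]")
  lines <- c(lines, "", "## Gene-set enrichment", "")
  if (!is.null(s$enrichment)) {
    for (st in names(s$enrichment)) {
      e <- s$enrichment[[st]]
      lines <- c(lines, if (e$nTested == 0 || e$nSignificant == 0)
        sprintf("- %s: no sets passed (%d tested)", st, e$nTested)
        else sprintf("- %s: %d of %d sets significant; top set %s", st,
                     e$nSignificant, e$nTested, e$topSet))
    }
  } else lines <- c(lines, "[missing: enrichment]")
  lines <- c(lines, "", "## Genotype separation", "")
  if (!is.null(s$separation)) {
    for (ref in names(s$separation$pvalues)) {
      p <- s$separation$pvalues[[ref]]
      lines <- c(lines, sprintf(
        "- brain_rudiment vs %s: observed %s, p = %s (seed %d)", ref,
        .fmtNum(p$observed), .fmtNum(p$pvalue), p$seed))
    }
    lines <- c(lines, sprintf("- signature test: p = %s",
                              .fmtNum(s$separation$signature$pvalue)))
  } else lines <- c(lines, "[missing: separation]")
  lines <- c(lines, "", "## Functional network", "")
  if (!is.null(s$network)) {
    n <- s$network
    lines <- c(lines,
      sprintf("- gold standard: %d positives, %d negatives (prior odds %s)",
              n$nPositives, n$nNegatives, .fmtNum(n$priorOdds)),
      sprintf("- strong edges (fold over prior): %d", n$nStrongEdges),
      sprintf("- seed gene %s: %d neighbors, %d TFs linked",
              n$seedGene, n$nNeighbors, n$nLinkedTFs),
      sprintf("- cross-validated AUC: %s", .fmtNum(n$cvAUC)),
      sprintf("- DE recapitulation: overlap %d, p = %s",
              n$deRecapitulationOverlap, .fmtNum(n$deRecapitulationP)))
  } else lines <- c(lines, "[missing: network]")
  writeLines(lines, file)
  invisible(file)
}
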