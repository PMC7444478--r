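## Synthetic-data generators. Every generator is a pure function of
## (arguments, seed), so identical calls are byte-identical.

#' Build a full-factorial developmental sample design
#'
#' Four stages x two genotypes with a configurable number of replicates
#' per cell (mirroring the 3-4 biologically independent measures of the
#' profiled design).
#'
#' @param nReplicates Either a single integer or a named vector with one
#'   entry per stage.
#' @return data.frame with columns `sample_id`, `stage`, `genotype`,
#'   `replicate`.
#' @export
#' @examples
#' head(makeDesign(3))
makeDesign <- function(nReplicates = 4) {
  if (length(nReplicates) == 1L)
    nReplicates <- setNames(rep(nReplicates, 4), .STAGES)
  if (!all(.STAGES %in% names(nReplicates)))
    stop("nReplicates must be scalar or named by stage")
  rows <- do.call(rbind, lapply(.STAGES, function(st)
    do.call(rbind, lapply(.GENOTYPES, function(gt) {
      r <- seq_len(nReplicates[[st]])
      data.frame(sample_id = sprintf("%s_%s_r%d", st, gt, r),
                 stage = st, genotype = gt, replicate = r,
                 stringsAsFactors = FALSE)
    }))))
  rownames(rows) <- NULL
  rows
}

#' Simulation parameters with study-analog defaults
#'
#' Defaults emulate the study conditions: a genotype effect of
#' `|log2FC| = 2` planted on 10\% of genes in the brain rudiment stage
#' only, common NB dispersion 0.1, library sizes log-uniform between 1
#' and 2 million, a 239-gene identity signature, 18 TF regulons, and a
#' module partition of the gene universe driving the evidence generator.
#'
#' @param deFraction Fraction of genes with a planted genotype effect,
#'   scalar or named per stage (default: brain_rudiment 0.1, others 0).
#' @param deLog2FC Absolute planted log2 fold change (sign randomised per
#'   gene).
#' @param dispersion Common negative-binomial dispersion `phi`
#'   (variance `mu + phi mu^2`); `0` gives Poisson counts.
#' @param librarySizeRange Numeric(2), library sizes are drawn
#'   log-uniformly within this range.
#' @param stageEffectFraction,stageEffectSD Fraction of genes carrying
#'   stage-specific baseline shifts and the SD (log2) of those shifts;
#'   set the fraction to 0 for a fully exchangeable null simulation.
#' @param baselineSD SD (log2) of per-gene baseline abundances.
#' @param nSignature Number of identity-signature genes.
#' @param signatureDEFraction Fraction of signature genes drawn from the
#'   planted brain-rudiment DE genes (so the signature carries genotype
#'   signal, as identity genes do in the perturbed tissue).
#' @param nTFs,regulonSize Number of TF regulons and targets per regulon.
#' @param nPerturbedTFs How many regulons are planted to draw most
#'   targets from coherently-signed DE genes.
#' @param regulonDEFraction Fraction of a perturbed regulon's targets
#'   taken from same-sign DE genes.
#' @param moduleSize Target module size; the gene universe is
#'   partitioned into roughly `nGenes / moduleSize` functional modules,
#'   so the within-module pair count grows linearly (not quadratically)
#'   with the universe.
#' @param nModules Explicit module count (overrides `moduleSize` when
#'   given).
#' @return A named list of parameters for [simulateCounts()].
#' @export
simulationParams <- function(deFraction = c(yolk_sac = 0, brain_rudiment = 0.1,
                                            neonate = 0, adult = 0),
                             deLog2FC = 2,
                             dispersion = 0.1,
                             librarySizeRange = c(1e6, 2e6),
                             stageEffectFraction = 0.3,
                             stageEffectSD = 1,
                             baselineSD = 1.2,
                             nSignature = 239,
                             signatureDEFraction = 0.5,
                             nTFs = 18,
                             regulonSize = 40,
                             nPerturbedTFs = 3,
                             regulonDEFraction = 0.8,
                             moduleSize = 15,
                             nModules = NULL) {
  deFraction <- unlist(deFraction)
  if (length(deFraction) == 1L)
    deFraction <- setNames(rep(deFraction, 4), .STAGES)
  if (is.null(names(deFraction)) && length(deFraction) == 4L)
    names(deFraction) <- .STAGES  # positional: stageLevels() order
  if (!all(.STAGES %in% names(deFraction)))
    stop("deFraction must be scalar, length-4, or named by stage")
  .assertScalarNumber(dispersion, "dispersion", lower = 0)
  if (length(librarySizeRange) != 2 || any(librarySizeRange <= 0) ||
      librarySizeRange[1] > librarySizeRange[2])
    stop("librarySizeRange must be an increasing positive pair")
  list(deFraction = deFraction[.STAGES], deLog2FC = deLog2FC,
       dispersion = dispersion, librarySizeRange = librarySizeRange,
       stageEffectFraction = stageEffectFraction,
       stageEffectSD = stageEffectSD, baselineSD = baselineSD,
       nSignature = nSignature, signatureDEFraction = signatureDEFraction,
       nTFs = nTFs, regulonSize = regulonSize,
       nPerturbedTFs = nPerturbedTFs, regulonDEFraction = regulonDEFraction,
       moduleSize = moduleSize, nModules = nModules)
}

#' Simulate negative-binomial counts with planted structure
#'
#' Generates gene-by-sample counts from an NB model with gene-specific
#' baselines, optional stage-specific shifts, and genotype (KI vs WT)
#' effects applied only to planted DE genes of each stage. Returns the
#' counts together with the full planted truth.
#'
#' @param nGenes Number of genes (>= 100).
#' @param design Sample design as from [makeDesign()]; must cover all four
#'   stages and both genotypes.
#' @param params Parameter list from [simulationParams()].
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return list with elements `experiment` ([MicrogliaExperiment-class])
#'   and `truth` ([SimulationTruth-class]).
#' @export
#' @examples
#' sim <- simulateCounts(200, makeDesign(2),
#'                       simulationParams(nSignature = 20), seed = 1)
#' sim$truth
simulateCounts <- function(nGenes, design, params = simulationParams(),
                           seed = 1) {
  if (nGenes < 100) stop("nGenes must be at least 100")
  ## re-validate (and re-name) parameters so that configs deserialized
  ## from YAML/JSON, which lose vector names, work unchanged
  params <- do.call(simulationParams,
                    params[names(params) %in%
                             names(formals(simulationParams))])
  .validateDesign(design)
  cells <- table(design$stage, design$genotype)
  if (!all(dim(cells) == c(4, 2)) || any(cells < 2))
    stop("design must cover all 4 stages x 2 genotypes with >= 2 replicates")
  if (params$nSignature > nGenes)
    stop("nSignature exceeds the gene universe")
  set.seed(as.integer(seed))
  genes <- sprintf("g%05d", seq_len(nGenes))
  nS <- nrow(design)

  baseline <- rnorm(nGenes, 0, params$baselineSD)

  stageEff <- matrix(0, nGenes, 4, dimnames = list(genes, .STAGES))
  nStageAffected <- round(params$stageEffectFraction * nGenes)
  if (nStageAffected > 0 && params$stageEffectSD > 0) {
    aff <- sample(genes, nStageAffected)
    stageEff[aff, ] <- rnorm(nStageAffected * 4, 0, params$stageEffectSD)
  }

  deGenes <- setNames(vector("list", 4), .STAGES)
  deEff <- matrix(0, nGenes, 4, dimnames = list(genes, .STAGES))
  for (st in .STAGES) {
    nDE <- round(params$deFraction[[st]] * nGenes)
    if (nDE > 0 && params$deLog2FC != 0) {
      gset <- sample(genes, nDE)
      eff <- sample(c(-1, 1), nDE, replace = TRUE) * params$deLog2FC
      deGenes[[st]] <- setNames(eff, gset)
      deEff[gset, st] <- eff
    } else deGenes[[st]] <- setNames(numeric(0), character(0))
  }

  nModules <- if (!is.null(params$nModules)) params$nModules
              else max(2L, round(nGenes / params$moduleSize))
  modules <- setNames(sample(rep(seq_len(nModules), length.out = nGenes)),
                      genes)

  brEff <- deGenes[["brain_rudiment"]]
  nSigDE <- min(round(params$nSignature * params$signatureDEFraction),
                length(brEff))
  sigDE <- if (nSigDE > 0) sample(names(brEff), nSigDE) else character(0)
  sigRest <- sample(setdiff(genes, sigDE), params$nSignature - nSigDE)
  signature <- sample(c(sigDE, sigRest))

  tfGenes <- sample(genes, params$nTFs)
  regulons <- setNames(vector("list", params$nTFs), tfGenes)
  upDE <- names(brEff)[brEff > 0]
  for (i in seq_len(params$nTFs)) {
    tf <- tfGenes[i]
    size <- min(params$regulonSize, nGenes - 1)
    if (i <= params$nPerturbedTFs && length(upDE) > 0) {
      pool <- setdiff(upDE, tf)
      nFromDE <- min(round(params$regulonDEFraction * size), length(pool))
      fromDE <- sample(pool, nFromDE)
      rest <- sample(setdiff(genes, c(tf, fromDE)), size - nFromDE)
      regulons[[i]] <- sample(c(fromDE, rest))
    } else {
      regulons[[i]] <- sample(setdiff(genes, tf), size)
    }
  }

  lsr <- params$librarySizeRange
  libSizes <- exp(runif(nS, log(lsr[1]), log(lsr[2])))

  logexpr <- matrix(0, nGenes, nS, dimnames = list(genes, design$sample_id))
  for (j in seq_len(nS)) {
    st <- design$stage[j]
    e <- baseline + stageEff[, st]
    if (design$genotype[j] == "KI") e <- e + deEff[, st]
    logexpr[, j] <- e
  }
  rel <- 2^logexpr
  prob <- sweep(rel, 2, colSums(rel), "/")
  mu <- sweep(prob, 2, libSizes, "*")

  counts <- if (params$dispersion > 0) {
    matrix(rnbinom(nGenes * nS, mu = mu, size = 1 / params$dispersion),
           nGenes, nS, dimnames = dimnames(mu))
  } else {
    matrix(rpois(nGenes * nS, mu), nGenes, nS, dimnames = dimnames(mu))
  }

  truth <- new("SimulationTruth", deGenes = deGenes,
               signatureGenes = signature, regulons = regulons,
               modules = modules, dispersion = params$dispersion,
               librarySizeRange = lsr)
  list(experiment = MicrogliaExperiment(counts, design), truth = truth)
}

#' Simulate a gene-set collection (GO-like sets, regulons, signature)
#'
#' Emits `nGoLike` random GO-term stand-ins with sizes uniform in
#' `sizeRange`, up to two effect-enriched sets drawn from planted DE
#' genes, the TF regulons and the identity signature copied from the
#' truth, and — when `nGoLike > 0` and the universe permits — one set of
#' size 9 and one of size 501 so that the 10–500 size filter has
#' boundary cases to drop.
#'
#' @param truth A [SimulationTruth-class].
#' @param nGoLike Number of random GO-like sets (0 gives regulons +
#'   signature only).
#' @param sizeRange Integer pair of GO-like set sizes, within
#'   `[2, nGenes]`.
#' @param seed Integer RNG seed.
#' @return A [GeneSetCollection-class].
#' @export
simulateGeneSets <- function(truth, nGoLike = 50, sizeRange = c(10, 500),
                             seed = 1) {
  genes <- geneUniverse(truth)
  if (sizeRange[1] > sizeRange[2]) stop("sizeRange is inverted")
  if (sizeRange[1] < 2 || sizeRange[2] > length(genes))
    stop("sizeRange must lie within [2, nGenes]")
  set.seed(as.integer(seed))
  sets <- list(); category <- character()
  if (nGoLike > 0) {
    sizes <- sample(seq(sizeRange[1], sizeRange[2]), nGoLike, replace = TRUE)
    for (i in seq_len(nGoLike)) {
      sets[[sprintf("GO_random_%03d", i)]] <- sample(genes, sizes[i])
    }
    for (st in names(truth@deGenes)) {
      eff <- truth@deGenes[[st]]
      up <- names(eff)[eff > 0]
      if (length(up) >= 10) {
        size <- min(max(20, length(up)), 100)
        nDE <- min(round(0.7 * size), length(up))
        members <- c(sample(up, nDE),
                     sample(setdiff(genes, up), size - nDE))
        sets[[sprintf("GO_enriched_%s", st)]] <- sample(members)
      }
    }
    sets[["GO_below_size_filter"]] <- sample(genes, 9)
    if (length(genes) >= 501)
      sets[["GO_above_size_filter"]] <- sample(genes, 501)
    category <- rep("go_like", length(sets))
  }
  for (tf in names(truth@regulons)) {
    sets[[paste0("regulon_", tf)]] <- truth@regulons[[tf]]
    category <- c(category, "tf_regulon")
  }
  sets[["microglia_identity_signature"]] <- truth@signatureGenes
  category <- c(category, "signature")
  GeneSetCollection(sets, category, universe = genes)
}

#' All within-module gene pairs of a simulation truth
#'
#' @param truth A [SimulationTruth-class].
#' @return Character vector of canonical pair keys.
#' @export
withinModulePairs <- function(truth) {
  mods <- split(names(truth@modules), truth@modules)
  unlist(lapply(mods, function(g) {
    if (length(g) < 2) return(character(0))
    g <- sort(g)
    cb <- combn(g, 2)
    paste(cb[1, ], cb[2, ], sep = "|")
  }), use.names = FALSE)
}

#' Simulate pairwise functional-evidence datasets
#'
#' Emulates (at desk scale) a compendium of functional-genomics datasets:
#' each dataset assigns every pair in a shared pair universe a Gaussian
#' score whose mean is `withinModuleSignal` higher for pairs inside the
#' same planted module. The pair universe contains all within-module
#' pairs (the superset of any gold standard built from the truth) plus
#' sampled between-module pairs.
#'
#' @param truth A [SimulationTruth-class].
#' @param nDatasets Number of datasets (>= 1).
#' @param withinModuleSignal Mean shift for within-module pairs, in
#'   (0, 1].
#' @param noiseSD Positive Gaussian noise SD.
#' @param seed Integer RNG seed.
#' @param betweenPerWithin Between-module pairs sampled per within-module
#'   pair.
#' @param coverage Fraction of the pair universe each dataset scores
#'   (pairs left out fall into the missing-evidence bin downstream).
#' @return An [EvidenceCollection-class].
#' @export
simulateEvidence <- function(truth, nDatasets = 10, withinModuleSignal = 0.8,
                             noiseSD = 0.5, seed = 1, betweenPerWithin = 4,
                             coverage = 1) {
  if (nDatasets < 1) stop("nDatasets must be >= 1")
  .assertScalarNumber(withinModuleSignal, "withinModuleSignal",
                      lower = 0, upper = 1, strictLower = TRUE)
  .assertScalarNumber(noiseSD, "noiseSD", lower = 0, strictLower = TRUE)
  set.seed(as.integer(seed))
  genes <- geneUniverse(truth)
  within <- withinModulePairs(truth)
  nBetween <- round(betweenPerWithin * length(within))
  cand <- character(0)
  while (length(cand) < nBetween) {
    a <- sample(genes, 2 * nBetween, replace = TRUE)
    b <- sample(genes, 2 * nBetween, replace = TRUE)
    keep <- a != b & truth@modules[a] != truth@modules[b]
    cand <- unique(c(cand, pairKey(a[keep], b[keep])))
  }
  between <- cand[seq_len(nBetween)]
  universe <- c(sort(within), sort(between))
  isWithin <- c(rep(TRUE, length(within)), rep(FALSE, length(between)))
  datasets <- list()
  for (d in seq_len(nDatasets)) {
    idx <- if (coverage < 1) {
      sort(sample(length(universe), round(coverage * length(universe))))
    } else seq_along(universe)
    ab <- splitPairKey(universe[idx])
    datasets[[sprintf("dataset_%02d", d)]] <- data.frame(
      geneA = ab[, 1], geneB = ab[, 2],
      score = rnorm(length(idx),
                    mean = ifelse(isWithin[idx], withinModuleSignal, 0),
                    sd = noiseSD),
      stringsAsFactors = FALSE)
  }
  EvidenceCollection(datasets, pairUniverse = universe)
}

#' Simulate a known-interaction pair list
#'
#' A uniform random subset (fraction `coverage`) of the truth's
#' within-module pairs — the "known functional interactions" input from
#' which positive gold-standard pairs are drawn.
#'
#' @param truth A [SimulationTruth-class].
#' @param coverage Fraction in (0, 1].
#' @param seed Integer RNG seed.
#' @return Character vector of canonical pair keys.
#' @export
simulateKnownInteractions <- function(truth, coverage = 1, seed = 1) {
  .assertScalarNumber(coverage, "coverage", lower = 0, upper = 1,
                      strictLower = TRUE)
  set.seed(as.integer(seed))
  within <- withinModulePairs(truth)
  n <- round(coverage * length(within))
  sort(sample(within, n))
}

#' Simulate an injective partial ortholog map
#'
#' @param genesA,genesB Non-empty gene universes (e.g. human and mouse
#'   ids).
#' @param mappedFraction Fraction of `genesA` that receives a mapping, in
#'   (0, 1].
#' @param seed Integer RNG seed.
#' @return data.frame with columns `from`, `to`; no gene appears twice in
#'   either column.
#' @export
simulateOrthologMap <- function(genesA, genesB, mappedFraction = 1, seed = 1) {
  if (!length(genesA) || !length(genesB)) stop("gene universes must be non-empty")
  .assertScalarNumber(mappedFraction, "mappedFraction", lower = 0, upper = 1,
                      strictLower = TRUE)
  n <- round(mappedFraction * length(genesA))
  if (n > length(genesB))
    stop("not enough target genes for an injective map")
  set.seed(as.integer(seed))
  data.frame(from = sample(genesA, n), to = sample(genesB, n),
             stringsAsFactors = FALSE)
}
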