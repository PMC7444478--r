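## Central S4 containers. MicrogliaExperiment wraps SummarizedExperiment;
## the remaining classes hold simulation truth, gene sets, pairwise
## evidence, the gold standard, the trained classifier and the scored
## network.

#' MicrogliaExperiment: stage/genotype-annotated count container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] whose
#' `colData` carries the developmental design (`sample_id`, `stage`,
#' `genotype`, `replicate`) and whose `"counts"` assay holds non-negative
#' integer gene-by-sample counts.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @aliases MicrogliaExperiment-class
#' @export
setClass("MicrogliaExperiment", contains = "SummarizedExperiment")

setValidity("MicrogliaExperiment", function(object) {
  msg <- character()
  if (!("counts" %in% assayNames(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be finite non-negative integers")
  }
  cd <- as.data.frame(colData(object))
  ok <- tryCatch({
    .validateDesign(cbind(sample_id = colnames(object), cd))
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (length(msg)) msg else TRUE
})

#' Construct a MicrogliaExperiment
#'
#' @param counts Non-negative integer matrix, genes as rows (rownames are
#'   gene ids), samples as columns.
#' @param design data.frame with columns `sample_id`, `stage`, `genotype`,
#'   `replicate`; `sample_id` must match `colnames(counts)` in order or be
#'   reorderable to them.
#' @return A [MicrogliaExperiment-class] object.
#' @export
#' @examples
#' design <- makeDesign(nReplicates = 2)
#' counts <- matrix(rpois(100 * nrow(design), 50), nrow = 100,
#'                  dimnames = list(sprintf("g%03d", 1:100), design$sample_id))
#' mge <- MicrogliaExperiment(counts, design)
#' mge
MicrogliaExperiment <- function(counts, design) {
  .validateDesign(design)
  design <- as.data.frame(design)
  if (is.null(colnames(counts)))
    stop("counts must have sample ids as colnames")
  if (!setequal(colnames(counts), design$sample_id))
    stop("colnames(counts) and design$sample_id disagree")
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  cd <- DataFrame(stage = as.character(design$stage),
                  genotype = as.character(design$genotype),
                  replicate = as.integer(design$replicate),
                  row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  new("MicrogliaExperiment", se)
}

#' Extract the sample design from a MicrogliaExperiment
#'
#' @param x A [MicrogliaExperiment-class].
#' @return data.frame with columns `sample_id`, `stage`, `genotype`,
#'   `replicate`.
#' @export
sampleDesign <- function(x) {
  stopifnot(is(x, "SummarizedExperiment"))
  cd <- as.data.frame(colData(x))
  data.frame(sample_id = colnames(x), stage = cd$stage,
             genotype = cd$genotype, replicate = cd$replicate,
             stringsAsFactors = FALSE)
}

#' SimulationTruth: planted ground truth of a simulated dataset
#'
#' Records every planted object so downstream recovery tests never need to
#' re-simulate: per-stage differential genes with signed log2 effects, the
#' identity-signature genes, TF regulons (named by the TF's own gene id),
#' the module partition of the gene universe, and the generating
#' dispersion / library-size range.
#'
#' @slot deGenes named list, one element per stage: named numeric vector
#'   of signed log2 genotype effects (names are gene ids).
#' @slot signatureGenes character, the planted identity-signature genes.
#' @slot regulons named list of character vectors; names are TF gene ids.
#' @slot modules named integer vector assigning every gene to a module.
#' @slot dispersion numeric, common NB dispersion used to generate counts.
#' @slot librarySizeRange numeric(2).
#' @aliases SimulationTruth-class
#' @export
setClass("SimulationTruth",
         representation(deGenes = "list", signatureGenes = "character",
                        regulons = "list", modules = "integer",
                        dispersion = "numeric",
                        librarySizeRange = "numeric"))

setValidity("SimulationTruth", function(object) {
  msg <- character()
  uni <- names(object@modules)
  if (is.null(uni) || anyDuplicated(uni))
    msg <- c(msg, "modules must be a named partition of the gene universe")
  for (st in names(object@deGenes)) {
    eff <- object@deGenes[[st]]
    if (length(eff) && (any(!is.finite(eff)) || any(eff == 0)))
      msg <- c(msg, sprintf("stage %s has non-finite or zero effects", st))
  }
  if (!all(object@signatureGenes %in% uni))
    msg <- c(msg, "signatureGenes outside the gene universe")
  if (length(object@dispersion) != 1 || object@dispersion < 0)
    msg <- c(msg, "dispersion must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationTruth-class gene universe of the simulation
#' @param truth A `SimulationTruth`.
#' @export
geneUniverse <- function(truth) names(truth@modules)

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@modules), "genes,",
      length(unique(object@modules)), "modules,",
      length(object@regulons), "regulons,",
      length(object@signatureGenes), "signature genes\n")
  nde <- vapply(object@deGenes, length, 1L)
  cat("  planted DE genes:",
      paste(sprintf("%s=%d", names(nde), nde), collapse = ", "), "\n")
})

#' GeneSetCollection: named gene sets with a category per set
#'
#' Categories are `go_like` (GO-term stand-ins), `tf_regulon`
#' (TRANSFAC-style TF target sets) and `signature` (the microglia
#' identity signature).
#'
#' @slot sets named list of character vectors (no empty set).
#' @slot category named character vector parallel to `sets`.
#' @aliases GeneSetCollection-class
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", category = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "sets must have unique names")
  if (any(vapply(object@sets, length, 1L) == 0))
    msg <- c(msg, "empty gene sets are not allowed")
  if (length(object@category) != length(object@sets))
    msg <- c(msg, "one category per set required")
  if (!all(object@category %in% c("go_like", "tf_regulon", "signature")))
    msg <- c(msg, "unknown category")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets Named list of character vectors.
#' @param category Character vector (length 1, recycled, or one per set).
#' @param universe Optional declared gene universe; members outside it are
#'   flagged with a warning (not removed).
#' @return A [GeneSetCollection-class].
#' @export
GeneSetCollection <- function(sets, category = "go_like", universe = NULL) {
  category <- rep_len(category, length(sets))
  names(category) <- names(sets)
  if (!is.null(universe)) {
    out <- vapply(sets, function(s) sum(!(s %in% universe)), 1L)
    if (any(out > 0))
      warning(sprintf("%d set(s) contain genes outside the declared universe",
                      sum(out > 0)))
  }
  new("GeneSetCollection", sets = lapply(sets, as.character),
      category = category)
}

#' @describeIn GeneSetCollection-class the named list of member vectors
#' @param x A `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection-class per-set categories
#' @export
setCategory <- function(x) x@category

setMethod("length", "GeneSetCollection", function(x) length(x@sets))
setMethod("names", "GeneSetCollection", function(x) names(x@sets))
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])
setMethod("show", "GeneSetCollection", function(object) {
  tab <- table(object@category)
  cat("GeneSetCollection with", length(object@sets), "sets (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
})

#' EvidenceCollection: per-dataset gene-pair evidence scores
#'
#' Each dataset scores a (possibly partial) subset of a shared pair
#' universe; pairs are stored with `geneA < geneB` lexicographically.
#'
#' @slot datasets named list of data.frames with columns `geneA`, `geneB`,
#'   `score`.
#' @slot pairUniverse character vector of canonical pair keys shared by
#'   the collection.
#' @aliases EvidenceCollection-class
#' @export
setClass("EvidenceCollection",
         representation(datasets = "list", pairUniverse = "character"))

setValidity("EvidenceCollection", function(object) {
  msg <- character()
  if (length(object@datasets) &&
      (is.null(names(object@datasets)) || anyDuplicated(names(object@datasets))))
    msg <- c(msg, "datasets must have unique names")
  for (nm in names(object@datasets)) {
    d <- object@datasets[[nm]]
    if (!all(c("geneA", "geneB", "score") %in% colnames(d))) {
      msg <- c(msg, sprintf("dataset %s lacks geneA/geneB/score", nm)); next
    }
    if (any(as.character(d$geneA) >= as.character(d$geneB)))
      msg <- c(msg, sprintf("dataset %s has non-canonical pair order", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EvidenceCollection
#'
#' @param datasets Named list of data.frames (`geneA`, `geneB`, `score`);
#'   pair order is canonicalised.
#' @param pairUniverse Optional character vector of pair keys; defaults to
#'   the union of all scored pairs.
#' @return An [EvidenceCollection-class].
#' @export
EvidenceCollection <- function(datasets, pairUniverse = NULL) {
  datasets <- lapply(datasets, function(d) {
    key <- pairKey(d$geneA, d$geneB)
    ab <- splitPairKey(key)
    data.frame(geneA = ab[, 1], geneB = ab[, 2], score = d$score,
               stringsAsFactors = FALSE)
  })
  if (is.null(pairUniverse))
    pairUniverse <- sort(unique(unlist(lapply(datasets, function(d)
      pairKey(d$geneA, d$geneB)))))
  new("EvidenceCollection", datasets = datasets,
      pairUniverse = as.character(pairUniverse))
}

#' @describeIn EvidenceCollection-class named list of dataset data.frames
#' @param x An `EvidenceCollection`.
#' @export
evidenceDatasets <- function(x) x@datasets

#' @describeIn EvidenceCollection-class shared pair universe (canonical keys)
#' @export
pairUniverse <- function(x) x@pairUniverse

setMethod("length", "EvidenceCollection", function(x) length(x@datasets))
setMethod("names", "EvidenceCollection", function(x) names(x@datasets))
setMethod("show", "EvidenceCollection", function(object) {
  cat("EvidenceCollection:", length(object@datasets), "datasets,",
      length(object@pairUniverse), "pairs in universe\n")
})

#' GoldStandard: labeled gene pairs for network training
#'
#' @slot positives character vector of canonical pair keys (functionally
#'   linked, both members context-expressed).
#' @slot negatives character vector of canonical pair keys.
#' @slot contextGenes character, the context-expressed gene set.
#' @aliases GoldStandard-class
#' @export
setClass("GoldStandard",
         representation(positives = "character", negatives = "character",
                        contextGenes = "character"))

setValidity("GoldStandard", function(object) {
  msg <- character()
  if (length(intersect(object@positives, object@negatives)))
    msg <- c(msg, "positives and negatives overlap")
  posGenes <- unique(as.vector(splitPairKey(object@positives)))
  if (length(object@positives) && !all(posGenes %in% object@contextGenes))
    msg <- c(msg, "positive pairs must lie inside contextGenes")
  if (length(msg)) msg else TRUE
})

#' @describeIn GoldStandard-class positive pair keys
#' @param x A `GoldStandard`.
#' @export
positivePairs <- function(x) x@positives

#' @describeIn GoldStandard-class negative pair keys
#' @export
negativePairs <- function(x) x@negatives

#' @describeIn GoldStandard-class context-expressed genes
#' @export
goldContextGenes <- function(x) x@contextGenes

setMethod("show", "GoldStandard", function(object) {
  cat("GoldStandard:", length(object@positives), "positives,",
      length(object@negatives), "negatives,",
      length(object@contextGenes), "context genes\n")
})

#' BinnedEvidence: quantile-discretised evidence
#'
#' Each dataset's continuous scores are mapped to bins `1..nBins`; pairs a
#' dataset does not cover map to the reserved missing bin `nBins + 1`.
#'
#' @slot bins named list of named integer vectors (pair key -> bin).
#' @slot binEdges named list of numeric vectors of interior quantile
#'   edges.
#' @slot nBins integer, number of observed-score bins.
#' @aliases BinnedEvidence-class
#' @export
setClass("BinnedEvidence",
         representation(bins = "list", binEdges = "list", nBins = "integer"))

setMethod("show", "BinnedEvidence", function(object) {
  cat("BinnedEvidence:", length(object@bins), "datasets,",
      object@nBins, "bins (+1 missing bin)\n")
})

#' NaiveBayesModel: trained evidence-integration classifier
#'
#' @slot priorOdds positive real, |positives| / |negatives| of the
#'   training gold standard.
#' @slot tables named list; per dataset a 2 x (nBins+1) probability matrix
#'   with rows `pos`, `neg`, columns bins 1..nBins plus the missing bin.
#' @slot binEdges named list of bin edges (copied from the binned
#'   evidence used in training).
#' @slot nBins integer.
#' @slot alpha positive real additive-smoothing pseudocount.
#' @aliases NaiveBayesModel-class
#' @export
setClass("NaiveBayesModel",
         representation(priorOdds = "numeric", tables = "list",
                        binEdges = "list", nBins = "integer",
                        alpha = "numeric"))

setValidity("NaiveBayesModel", function(object) {
  msg <- character()
  if (object@priorOdds <= 0 || !is.finite(object@priorOdds))
    msg <- c(msg, "priorOdds must be positive and finite")
  for (nm in names(object@tables)) {
    tb <- object@tables[[nm]]
    if (any(tb <= 0)) msg <- c(msg, sprintf("dataset %s: zero probability", nm))
    if (any(abs(rowSums(tb) - 1) > 1e-8))
      msg <- c(msg, sprintf("dataset %s: rows must sum to 1", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NaiveBayesModel-class prior odds of the trained model
#' @param x A `NaiveBayesModel` or [FunctionalNetwork-class].
#' @export
priorOdds <- function(x) x@priorOdds

setMethod("show", "NaiveBayesModel", function(object) {
  cat("NaiveBayesModel:", length(object@tables), "evidence datasets,",
      object@nBins, "bins, prior odds",
      format(object@priorOdds, digits = 4), "\n")
})

#' FunctionalNetwork: posterior-odds weighted gene-pair network
#'
#' @slot edges data.frame with columns `geneA`, `geneB` (canonical
#'   order), `posteriorOdds`, `foldOverPrior`.
#' @slot priorOdds positive real prior odds of the generating model.
#' @slot metadata list of bookkeeping values (e.g. `nDropped` after
#'   ortholog mapping).
#' @aliases FunctionalNetwork-class
#' @export
setClass("FunctionalNetwork",
         representation(edges = "data.frame", priorOdds = "numeric",
                        metadata = "list"))

setValidity("FunctionalNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("geneA", "geneB", "posteriorOdds", "foldOverPrior")
  if (!all(need %in% colnames(e)))
    msg <- c(msg, "edges need geneA/geneB/posteriorOdds/foldOverPrior")
  else {
    if (nrow(e) && any(as.character(e$geneA) >= as.character(e$geneB)))
      msg <- c(msg, "edges must be stored in canonical (lexicographic) order")
    if (nrow(e) && (any(!is.finite(e$posteriorOdds)) || any(e$posteriorOdds <= 0)))
      msg <- c(msg, "posteriorOdds must be finite and positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FunctionalNetwork from an edge table
#'
#' @param edges data.frame with `geneA`, `geneB`, `posteriorOdds` (and
#'   optionally `foldOverPrior`, recomputed if absent).
#' @param priorOdds Positive prior odds.
#' @param metadata Optional list.
#' @return A [FunctionalNetwork-class].
#' @export
FunctionalNetwork <- function(edges, priorOdds, metadata = list()) {
  if (nrow(edges)) {
    key <- pairKey(edges$geneA, edges$geneB)
    ab <- splitPairKey(key)
    edges$geneA <- ab[, 1]; edges$geneB <- ab[, 2]
    if (is.null(edges$foldOverPrior))
      edges$foldOverPrior <- edges$posteriorOdds / priorOdds
    edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(geneA = character(), geneB = character(),
                        posteriorOdds = numeric(), foldOverPrior = numeric())
  }
  new("FunctionalNetwork", edges = edges, priorOdds = priorOdds,
      metadata = metadata)
}

#' @describeIn FunctionalNetwork-class the edge table
#' @param x A `FunctionalNetwork`.
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "FunctionalNetwork", function(object) {
  cat("FunctionalNetwork:", nrow(object@edges), "edges, prior odds",
      format(object@priorOdds, digits = 4), "\n")
})

#' PermutationTestResult: a Phipson-Smyth permutation test outcome
#'
#' The p-value is `(b + 1) / (nPerm + 1)` where `b` counts permutation
#' statistics greater than or equal to the observed one; it can therefore
#' never be exactly zero.
#'
#' @slot observed numeric observed statistic.
#' @slot b integer count of permutation statistics >= observed.
#' @slot nPerm integer number of permutations.
#' @slot pvalue numeric.
#' @slot seed integer seed used for the permutation stream.
#' @aliases PermutationTestResult-class
#' @export
setClass("PermutationTestResult",
         representation(observed = "numeric", b = "integer",
                        nPerm = "integer", pvalue = "numeric",
                        seed = "integer"))

setValidity("PermutationTestResult", function(object) {
  p <- (object@b + 1) / (object@nPerm + 1)
  if (abs(p - object@pvalue) > 1e-12)
    return("pvalue must equal (b + 1) / (nPerm + 1)")
  TRUE
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf(
    "PermutationTestResult: observed = %.6g, b = %d / %d, p = %.6g\n",
    object@observed, object@b, object@nPerm, object@pvalue))
})

#' @describeIn PermutationTestResult-class p-value accessor
#' @param x A `PermutationTestResult`.
#' @export
pvalue <- function(x) x@pvalue

#' @describeIn PermutationTestResult-class observed-statistic accessor
#' @export
observedStatistic <- function(x) x@observed
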