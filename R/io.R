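## Plain-text readers/writers for the pipeline's external interfaces:
## counts + design TSV, GMT gene sets, evidence edge lists, network
## edges, model JSON.

.writeTSV <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write counts and design as TSV
#'
#' Counts: genes as rows, first column `gene`, one column per sample.
#' Design: columns `sample_id`, `stage`, `genotype`, `replicate`.
#'
#' @param countsFile,designFile File paths.
#' @return `readCounts` returns a [MicrogliaExperiment-class].
#' @export
readCounts <- function(countsFile, designFile) {
  tab <- read.delim(countsFile, check.names = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  storage.mode(counts) <- "integer"
  design <- read.delim(designFile)
  MicrogliaExperiment(counts, design)
}

#' @rdname readCounts
#' @param x A [MicrogliaExperiment-class].
#' @export
writeCounts <- function(x, countsFile, designFile) {
  counts <- assay(x, "counts")
  .writeTSV(data.frame(gene = rownames(counts), counts,
                       check.names = FALSE), countsFile)
  .writeTSV(sampleDesign(x), designFile)
  invisible(c(countsFile, designFile))
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, tab-separated members. The
#' description field carries the set category so collections round-trip.
#'
#' @param file File path.
#' @return `readGMT` returns a [GeneSetCollection-class].
#' @export
readGMT <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-c(1, 2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  category <- vapply(parts, `[`, character(1), 2)
  category[!(category %in% c("go_like", "tf_regulon", "signature"))] <-
    "go_like"
  GeneSetCollection(sets, category)
}

#' @rdname readGMT
#' @param sets A [GeneSetCollection-class].
#' @export
writeGMT <- function(sets, file) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, setCategory(sets)[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read / write evidence collections as per-dataset TSV edge lists
#'
#' Each dataset is one file `<name>.tsv` with columns `gene_a`,
#' `gene_b`, `score`, pairs stored with `gene_a < gene_b`
#' lexicographically.
#'
#' @param dir Directory holding (or to hold) the dataset files.
#' @return `readEvidenceDir` returns an [EvidenceCollection-class].
#' @export
readEvidenceDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv evidence files in ", dir)
  datasets <- lapply(files, function(f) {
    d <- read.delim(f)
    data.frame(geneA = d$gene_a, geneB = d$gene_b, score = d$score,
               stringsAsFactors = FALSE)
  })
  names(datasets) <- sub("\\.tsv$", "", basename(files))
  EvidenceCollection(datasets)
}

#' @rdname readEvidenceDir
#' @param evidence An [EvidenceCollection-class].
#' @export
writeEvidenceDir <- function(evidence, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(evidence)) {
    d <- evidenceDatasets(evidence)[[nm]]
    .writeTSV(data.frame(gene_a = d$geneA, gene_b = d$geneB,
                         score = d$score),
              file.path(dir, paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' Read / write a functional network as a TSV edge table
#'
#' Columns `gene_a`, `gene_b`, `posterior_odds`, `fold_over_prior`; the
#' prior odds travel in a header comment line.
#'
#' @param file File path.
#' @return `readNetwork` returns a [FunctionalNetwork-class].
#' @export
readNetwork <- function(file) {
  first <- readLines(file, n = 1)
  prior <- as.numeric(sub("^# prior_odds=", "", first))
  e <- read.delim(file, comment.char = "#")
  FunctionalNetwork(
    data.frame(geneA = as.character(e$gene_a),
               geneB = as.character(e$gene_b),
               posteriorOdds = e$posterior_odds,
               foldOverPrior = e$fold_over_prior,
               stringsAsFactors = FALSE),
    priorOdds = prior)
}

#' @rdname readNetwork
#' @param net A [FunctionalNetwork-class].
#' @export
writeNetwork <- function(net, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# prior_odds=%.17g", net@priorOdds), con)
  e <- networkEdges(net)
  write.table(data.frame(gene_a = e$geneA, gene_b = e$geneB,
                         posterior_odds = e$posteriorOdds,
                         fold_over_prior = e$foldOverPrior),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Serialise / restore a trained naive-Bayes model as JSON
#'
#' @param file File path.
#' @return `readNaiveBayesModel` returns a [NaiveBayesModel-class].
#' @export
readNaiveBayesModel <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  tables <- lapply(x$tables, function(tb) {
    m <- rbind(pos = as.numeric(tb$pos), neg = as.numeric(tb$neg))
    colnames(m) <- c(paste0("bin", seq_len(x$nBins)), "missing")
    m
  })
  new("NaiveBayesModel", priorOdds = x$priorOdds, tables = tables,
      binEdges = lapply(x$binEdges, as.numeric),
      nBins = as.integer(x$nBins), alpha = x$alpha)
}

#' @rdname readNaiveBayesModel
#' @param model A [NaiveBayesModel-class].
#' @export
writeNaiveBayesModel <- function(model, file) {
  x <- list(priorOdds = model@priorOdds, nBins = model@nBins,
            alpha = model@alpha,
            binEdges = model@binEdges,
            tables = lapply(model@tables, function(tb)
              list(pos = unname(tb["pos", ]), neg = unname(tb["neg", ]))))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
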