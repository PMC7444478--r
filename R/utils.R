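## Small shared helpers: vocabularies, pair keys, seed streams.

.STAGES <- c("yolk_sac", "brain_rudiment", "neonate", "adult")
.GENOTYPES <- c("WT", "KI")

#' Developmental stage and genotype vocabularies
#'
#' The four developmental stages and two genotypes recognised throughout
#' the package. All `stage` / `genotype` arguments and design columns must
#' use these values.
#'
#' @return Character vector of levels.
#' @export
#' @examples
#' stageLevels()
#' genotypeLevels()
stageLevels <- function() .STAGES

#' @rdname stageLevels
#' @export
genotypeLevels <- function() .GENOTYPES

#' Canonical unordered gene-pair keys
#'
#' Gene pairs are stored throughout as a single string key
#' `"<a>|<b>"` with the two members in lexicographic order, so that an
#' unordered pair has exactly one representation.
#'
#' @param a,b Character vectors of gene ids (recycled to common length).
#' @return Character vector of canonical keys.
#' @export
#' @examples
#' pairKey(c("g2", "g1"), c("g1", "g3"))
pairKey <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (any(a == b)) stop("self-pairs are not allowed")
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Split canonical pair keys back into a two-column matrix
#'
#' @param keys Character vector of keys produced by [pairKey()].
#' @return Character matrix with columns `geneA`, `geneB`.
#' @export
splitPairKey <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(out) <- c("geneA", "geneB")
  out
}

## Deterministic child-seed derivation: child_i = (master * 48271 + i * 7919)
## mod (2^31 - 1), kept strictly positive. Used wherever one master seed
## must drive several independent reproducible streams (subsample
## replicates, pipeline stages).
.childSeed <- function(master, index) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + as.double(index) * 7919
  s <- s %% m
  as.integer(if (s == 0) 1 else s)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strictLower = FALSE, strictUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  lowOK <- if (strictLower) x > lower else x >= lower
  highOK <- if (strictUpper) x < upper else x <= upper
  if (!lowOK || !highOK)
    stop(sprintf("'%s' = %g is outside its allowed range", name, x))
  invisible(x)
}

## design validation shared by the constructor and the simulator; errors
## name the offending sample.
.validateDesign <- function(design) {
  need <- c("sample_id", "stage", "genotype", "replicate")
  if (!is.data.frame(design) || !all(need %in% colnames(design)))
    stop("design must be a data.frame with columns ",
         paste(need, collapse = ", "))
  ids <- as.character(design$sample_id)
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1])
  badStage <- !(as.character(design$stage) %in% .STAGES)
  if (any(badStage))
    stop(sprintf("sample '%s' has unknown stage '%s'",
                 ids[badStage][1], as.character(design$stage)[badStage][1]))
  badGt <- !(as.character(design$genotype) %in% .GENOTYPES)
  if (any(badGt))
    stop(sprintf("sample '%s' has unknown genotype '%s'",
                 ids[badGt][1], as.character(design$genotype)[badGt][1]))
  rep_ <- design$replicate
  if (any(!is.finite(rep_)) || any(rep_ < 1) || any(rep_ != round(rep_)))
    stop("replicate must be a positive integer")
  invisible(design)
}

.rowVars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}
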