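#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet readDNAStringSet
#'   writeXStringSet pairwiseAlignment nmatch score AAString
#' @importFrom BiocGenerics start end width
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats hclust dist as.dendrogram sd setNames runif
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom grDevices png dev.off
#' @useDynLib ironScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The twelve functional categories of the iron-gene schema
#'
#' Fixed, ordered vector of the functional category labels used throughout
#' the package: iron transport, heme oxygenases, heme transport (including
#' transferrin/lactoferrin receptors), siderophore synthesis and transport,
#' iron gene regulation, iron oxidation, the ambiguous
#' oxidation-or-reduction class reserved for the MtoAB/PioAB-like and
#' cluster-3 Cyc2 families, iron reduction, probable iron reduction, iron
#' storage, and magnetosome formation.
#'
#' @return Character vector of length 12, in fixed order.
#' @export
#' @examples
#' categorySchema()
categorySchema <- function() {
  c("iron_transport",
    "heme_oxygenase",
    "heme_transport",
    "siderophore_synthesis",
    "siderophore_transport",
    "iron_gene_regulation",
    "iron_oxidation",
    "possible_iron_oxidation_and_possible_iron_reduction",
    "iron_reduction",
    "probable_iron_reduction",
    "iron_storage",
    "magnetosome_formation")
}

#' GeneCalls: predicted proteins of one sample with contig coordinates
#'
#' Container for the gene calls of a single genome or metagenome sample:
#' a table of per-gene metadata (contig, ordinal index along the contig,
#' 1-based inclusive nucleotide coordinates, strand) paired with the
#' translated protein sequences, plus the total number of predicted
#' protein-coding genes used as the normalization denominator.
#'
#' @slot sampleId single sample identifier.
#' @slot calls data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{index} (1-based ordinal along the contig, increasing by start),
#'   \code{start}, \code{end} (1-based inclusive, NA when unknown),
#'   \code{strand} ("+", "-", or NA).
#' @slot proteins \code{AAStringSet}, parallel to \code{calls}; stop
#'   codons already stripped.
#' @slot orfCount total predicted protein-coding genes in the sample.
#' @export
setClass("GeneCalls",
         slots = c(sampleId = "character",
                   calls    = "data.frame",
                   proteins = "AAStringSet",
                   orfCount = "integer"))

setValidity("GeneCalls", function(object) {
  msg <- character()
  cl <- object@calls
  need <- c("gene_id", "contig_id", "index", "start", "end", "strand")
  if (!all(need %in% names(cl)))
    msg <- c(msg, paste("calls must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(cl) != length(object@proteins))
      msg <- c(msg, "calls and proteins must be parallel")
    if (anyDuplicated(cl$gene_id))
      msg <- c(msg, "gene_id must be unique")
    if (any(Biostrings::width(object@proteins) == 0))
      msg <- c(msg, "empty protein sequence")
    bad <- !is.na(cl$start) & !is.na(cl$end) & cl$start > cl$end
    if (any(bad)) msg <- c(msg, "start > end for some gene calls")
    for (ct in unique(cl$contig_id)) {
      ix <- cl$index[cl$contig_id == ct]
      if (anyDuplicated(ix) || any(ix < 1))
        msg <- c(msg, sprintf("indices on contig '%s' must be unique and >= 1", ct))
    }
  }
  if (length(object@orfCount) != 1 || is.na(object@orfCount) || object@orfCount < 1)
    msg <- c(msg, "orfCount must be a single positive integer")
  else if (object@orfCount < nrow(cl))
    msg <- c(msg, "orfCount cannot be smaller than the number of gene calls")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneCalls construct a GeneCalls object.
#' @param sampleId sample identifier.
#' @param calls gene table (see slot documentation).
#' @param proteins \code{AAStringSet} (or named character vector) of
#'   translations, parallel to \code{calls}.
#' @param orfCount total predicted ORFs; defaults to \code{nrow(calls)}.
#' @export
GeneCalls <- function(sampleId, calls, proteins, orfCount = nrow(calls)) {
  if (!is(proteins, "AAStringSet")) proteins <- AAStringSet(proteins)
  # stop codons are not part of the scored translation
  proteins <- AAStringSet(gsub("\\*", "", as.character(proteins)))
  names(proteins) <- calls$gene_id
  calls$index <- as.integer(calls$index)
  o <- order(calls$contig_id, calls$index)
  new("GeneCalls", sampleId = as.character(sampleId),
      calls = calls[o, , drop = FALSE],
      proteins = proteins[o],
      orfCount = as.integer(orfCount))
}

#' @describeIn GeneCalls sample identifier.
#' @param x a \code{GeneCalls} object.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn GeneCalls total predicted protein-coding genes.
#' @export
orfCount <- function(x) x@orfCount

#' @describeIn GeneCalls the per-gene table.
#' @export
geneTable <- function(x) x@calls

#' @describeIn GeneCalls translated protein sequences.
#' @export
proteins <- function(x) x@proteins

setMethod("show", "GeneCalls", function(object) {
  cat("GeneCalls for sample", sQuote(object@sampleId), "\n")
  cat(" ", nrow(object@calls), "gene calls on",
      length(unique(object@calls$contig_id)), "contig(s);",
      object@orfCount, "predicted ORFs\n")
  if (all(is.na(object@calls$start)))
    cat("  (no coordinates: neighborhoods degenerate to single genes)\n")
})

setMethod("length", "GeneCalls", function(x) nrow(x@calls))

#' ProfileHMM: a protein-family profile hidden Markov model
#'
#' Match/insert emission probabilities, node transition probabilities,
#' background residue frequencies, and the calibrated acceptance bit-score
#' cutoff for one protein family. Scoring is uni-local Viterbi in log2
#' space (see \code{\link{viterbiBits}}).
#'
#' @slot name model name.
#' @slot M number of match states.
#' @slot alphabet the 20 amino acids, canonical order.
#' @slot matchEmit M x 20 matrix of match emission probabilities.
#' @slot insertEmit M x 20 matrix of insert emission probabilities.
#' @slot transitions M x 7 matrix, columns \code{MM, MI, MD, IM, II, DM,
#'   DD}; row i holds node i's transitions toward node i+1.
#' @slot background length-20 null-model residue frequencies.
#' @slot bitCutoff calibrated acceptance threshold in bits (NA until set).
#' @export
setClass("ProfileHMM",
         slots = c(name = "character", M = "integer",
                   alphabet = "character",
                   matchEmit = "matrix", insertEmit = "matrix",
                   transitions = "matrix", background = "numeric",
                   bitCutoff = "numeric"))

AMINO <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

setValidity("ProfileHMM", function(object) {
  msg <- character()
  tol <- 1e-6
  M <- object@M
  if (M < 1) msg <- c(msg, "M must be >= 1")
  if (!identical(object@alphabet, AMINO))
    msg <- c(msg, "alphabet must be the 20 amino acids in canonical order")
  if (!all(dim(object@matchEmit) == c(M, 20)))
    msg <- c(msg, "matchEmit must be M x 20")
  else if (any(abs(rowSums(object@matchEmit) - 1) > tol))
    msg <- c(msg, "match emission rows must sum to 1")
  if (!all(dim(object@insertEmit) == c(M, 20)))
    msg <- c(msg, "insertEmit must be M x 20")
  else if (any(abs(rowSums(object@insertEmit) - 1) > tol))
    msg <- c(msg, "insert emission rows must sum to 1")
  if (!all(dim(object@transitions) == c(M, 7)))
    msg <- c(msg, "transitions must be M x 7")
  else {
    tr <- object@transitions
    grp <- cbind(tr[, 1] + tr[, 2] + tr[, 3],   # M -> {M,I,D}
                 tr[, 4] + tr[, 5],             # I -> {M,I}
                 tr[, 6] + tr[, 7])             # D -> {M,D}
    if (any(abs(grp - 1) > tol))
      msg <- c(msg, "each transition group must sum to 1")
  }
  if (length(object@background) != 20 ||
      abs(sum(object@background) - 1) > tol)
    msg <- c(msg, "background must be 20 frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileHMM construct a ProfileHMM.
#' @param name model name.
#' @param matchEmit,insertEmit,transitions,background,bitCutoff see slots.
#' @export
ProfileHMM <- function(name, matchEmit, insertEmit = NULL,
                       transitions = NULL, background = rep(1 / 20, 20),
                       bitCutoff = NA_real_) {
  M <- nrow(matchEmit)
  if (is.null(insertEmit))
    insertEmit <- matrix(rep(background, each = M), nrow = M)
  if (is.null(transitions)) {
    transitions <- matrix(rep(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1), each = M),
                          nrow = M)
    transitions[M, ] <- c(1, 0, 0, 1, 0, 1, 0)  # final node exits
  }
  colnames(transitions) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  colnames(matchEmit) <- colnames(insertEmit) <- AMINO
  new("ProfileHMM", name = as.character(name), M = as.integer(M),
      alphabet = AMINO, matchEmit = matchEmit, insertEmit = insertEmit,
      transitions = transitions, background = background,
      bitCutoff = as.numeric(bitCutoff))
}

#' @describeIn ProfileHMM number of match states.
#' @param x a \code{ProfileHMM}.
#' @export
modelLength <- function(x) x@M

#' @describeIn ProfileHMM calibrated bit-score cutoff (NA if unset).
#' @export
bitCutoff <- function(x) x@bitCutoff

#' @describeIn ProfileHMM return a copy with the cutoff set.
#' @param value new cutoff in bits.
#' @export
`bitCutoff<-` <- function(x, value) {
  x@bitCutoff <- as.numeric(value)
  x
}

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM", sQuote(object@name), "with", object@M, "match states;",
      if (is.na(object@bitCutoff)) "no bit cutoff set"
      else paste("bit cutoff", format(object@bitCutoff)), "\n")
})
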