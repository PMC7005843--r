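## Database-construction computations: homolog gathering filters,
## identity-based dereplication of seed sets, and per-model bit-score
## cutoff selection from labelled search results. Seed gathering against
## public repositories and alignment/model building are documented as an
## external recipe (see the methods vignette), not tested operations.

#' Filter homolog search hits by identity and query coverage
#'
#' Retains hits with percent identity at or above \code{minIdentity} and
#' query coverage at or above \code{minCoverage} — the gathering rule
#' used when expanding curated seed sequences with database homologs.
#'
#' @param hits data.frame with columns \code{query}, \code{subject},
#'   \code{identity} (percent, 0-100) and \code{coverage} (fraction of
#'   the query aligned, 0-1).
#' @param minIdentity minimum percent amino-acid identity (default 35).
#' @param minCoverage minimum fraction of the query length (default 0.7).
#' @return The retained rows.
#' @export
filterHomologs <- function(hits, minIdentity = 35, minCoverage = 0.7) {
  if (minIdentity < 0 || minIdentity > 100 ||
      minCoverage < 0 || minCoverage > 1)
    stop("thresholds out of bounds", call. = FALSE)
  keep <- hits$identity >= minIdentity & hits$coverage >= minCoverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global percent identity of two proteins
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11 / extend 1);
#' identity is matches divided by alignment columns (gaps included).
#'
#' @param a,b protein strings.
#' @return Percent identity in [0, 100].
#' @export
globalPercentIdentity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .substMatrix("BLOSUM62"),
    gapOpening = 11, gapExtension = 1)
  # alignment length including gap columns
  ncol <- nchar(as.character(Biostrings::alignedPattern(al)))
  100 * Biostrings::nmatch(al) / ncol
}

#' Collapse a protein set to identity-based representatives
#'
#' Greedy clustering by descending sequence length: each sequence joins
#' the first existing representative to which its global percent
#' identity meets the threshold, otherwise it founds a new cluster. The
#' representatives are returned. Used to remove over-represented
#' sequences before alignment and model building.
#'
#' @param seqs character vector (or \code{AAStringSet}) of proteins.
#' @param threshold percent identity collapse threshold, in (0, 100]
#'   (default 70).
#' @param seed accepted for interface symmetry; the greedy pass is
#'   deterministic (ties in length keep input order).
#' @return Character vector of representative sequences (named if the
#'   input was named).
#' @export
dereplicate <- function(seqs, threshold = 70, seed = NULL) {
  if (threshold <= 0 || threshold > 100)
    stop("threshold must be in (0, 100]", call. = FALSE)
  seqs <- as.character(seqs)
  if (!length(seqs)) return(character(0))
  o <- order(-nchar(seqs), seq_along(seqs))
  reps <- integer(0)
  for (i in o) {
    joined <- FALSE
    for (r in reps) {
      if (globalPercentIdentity(seqs[i], seqs[r]) >= threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  seqs[sort(reps)]
}

#' Choose a bit-score cutoff separating true from false positives
#'
#' When the classes are separable (or no false positives are known) the
#' cutoff is the minimum true-positive score. Otherwise the cutoff is
#' the candidate threshold (over the distinct observed scores) that
#' maximizes balanced accuracy — mean of sensitivity (true scores at or
#' above the threshold) and specificity (false scores below it) — with
#' ties resolved toward the larger threshold, favoring precision.
#'
#' @param trueScores bit scores of curated true positives (non-empty).
#' @param falseScores bit scores of known false positives (may be
#'   empty).
#' @return The cutoff in bits.
#' @export
chooseCutoff <- function(trueScores, falseScores = numeric(0)) {
  if (!length(trueScores)) stop("no true-positive scores", call. = FALSE)
  if (!length(falseScores) || min(trueScores) > max(falseScores))
    return(min(trueScores))
  cand <- sort(unique(c(trueScores, falseScores)))
  ba <- vapply(cand, function(t)
    (mean(trueScores >= t) + mean(falseScores < t)) / 2, numeric(1))
  max(cand[ba >= max(ba) - 1e-12])
}

#' Read labelled scores from a two-column TSV
#'
#' @param path TSV with columns \code{score} and \code{label} (values
#'   \code{TP} / \code{FP}).
#' @return List with \code{true_scores} and \code{false_scores}.
#' @export
readLabeledScores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("score", "label") %in% names(df)))
    stop("expected columns 'score' and 'label'", call. = FALSE)
  if (!all(df$label %in% c("TP", "FP")))
    stop("labels must be TP or FP", call. = FALSE)
  list(true_scores = df$score[df$label == "TP"],
       false_scores = df$score[df$label == "FP"])
}
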