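## Pairwise local-alignment fallback for families that lack reliable
## profile HMMs (S-layer proteins, porin-cytochrome operon members).
## The contract is the e-value acceptance threshold (default 1e-10);
## scores come from affine-gap Smith-Waterman under BLOSUM62 with the
## gapped Karlin-Altschul constants recorded in the configuration.

.substMatrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal local alignment of two proteins (affine gaps)
#'
#' Smith-Waterman local alignment score under a substitution matrix with
#' affine gap penalties (a gap of length k costs
#' \code{gapOpen + k * gapExtend}). The score of the empty alignment is 0,
#' so the result is never negative.
#'
#' @param query,target protein strings (non-empty).
#' @param matrix substitution matrix name (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend positive gap penalties.
#' @param config scoring constants for the bit conversion; see
#'   \code{\link{ironScanDefaults}}.
#' @return List with \code{score} (raw, substitution-matrix units),
#'   \code{bits}, and the aligned spans \code{query_span},
#'   \code{target_span} (NULL for an empty alignment).
#' @export
smithWaterman <- function(query, target, matrix = "BLOSUM62",
                          gapOpen = 11, gapExtend = 1,
                          config = ironScanDefaults()) {
  if (!nzchar(query) || !nzchar(target))
    stop("empty sequence", call. = FALSE)
  if (gapOpen <= 0 || gapExtend <= 0)
    stop("gap penalties must be positive", call. = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = .substMatrix(matrix),
    gapOpening = gapOpen, gapExtension = gapExtend)
  raw <- Biostrings::score(al)
  if (raw <= 0)
    return(list(score = 0, bits = .bitsFromRaw(0, config),
                query_span = NULL, target_span = NULL))
  pr <- methods::slot(al, "pattern")@range
  sr <- methods::slot(al, "subject")@range
  list(score = raw, bits = .bitsFromRaw(raw, config),
       query_span = c(BiocGenerics::start(pr), BiocGenerics::end(pr)),
       target_span = c(BiocGenerics::start(sr), BiocGenerics::end(sr)))
}

# gapped Karlin-Altschul bit scale: bits = (lambda * S - ln K) / ln 2
.bitsFromRaw <- function(raw, config = ironScanDefaults()) {
  (config$lambda * raw - log(config$K)) / log(2)
}

#' Expected chance hits for a bit score in a given search space
#'
#' \code{E = m * n * 2^(-bits)} for query length \code{m} and total
#' reference residues \code{n} (no length or edge corrections).
#'
#' @param bits bit score.
#' @param m query length in residues (>= 1).
#' @param n total residues in the reference set (>= 1).
#' @return The e-value.
#' @export
evalueFromBits <- function(bits, m, n) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1", call. = FALSE)
  m * n * 2^(-bits)
}

#' Homology search of a sample against one family's reference set
#'
#' Aligns every gene against every reference sequence of a
#' homology-method family, converts scores to e-values over the search
#' space m x (total reference residues), retains hits at or below the
#' family's e-value cutoff, and keeps the best reference per gene.
#'
#' @param genes a \code{\link{GeneCalls}} object.
#' @param db an \code{\link{IronFamilyDb}}.
#' @param family a homology-method family id.
#' @param cutoff e-value acceptance threshold; defaults to the family's
#'   manifest cutoff.
#' @return data.frame with columns \code{gene_id}, \code{reference},
#'   \code{score}, \code{bits}, \code{evalue} (one row per retained
#'   gene).
#' @export
fallbackSearch <- function(genes, db, family,
                           cutoff = NULL) {
  fam <- familyTable(db)
  i <- match(family, fam$family_id)
  if (is.na(i) || fam$method[i] != "homology")
    stop("'", family, "' is not a homology-method family", call. = FALSE)
  if (is.null(cutoff)) cutoff <- fam$cutoff[i]
  refs <- refSet(db, family)
  if (!length(refs)) stop("empty reference set for '", family, "'",
                          call. = FALSE)
  cfg <- dbConfig(db)
  n <- sum(Biostrings::width(refs))
  aa <- proteins(genes)
  mat <- .substMatrix(cfg$substitution_matrix)
  best <- NULL
  for (r in seq_along(refs)) {
    al <- Biostrings::pairwiseAlignment(
      aa, refs[[r]], type = "local", substitutionMatrix = mat,
      gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
    raw <- pmax(Biostrings::score(al), 0)
    bits <- .bitsFromRaw(raw, cfg)
    ev <- evalueFromBits(bits, Biostrings::width(aa), n)
    df <- data.frame(gene_id = geneTable(genes)$gene_id,
                     reference = names(refs)[r], score = raw, bits = bits,
                     evalue = ev, stringsAsFactors = FALSE)
    best <- if (is.null(best)) df else {
      swap <- df$evalue < best$evalue
      best[swap, ] <- df[swap, ]
      best
    }
  }
  out <- best[best$evalue <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
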