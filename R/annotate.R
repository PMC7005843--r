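## Per-gene detection: HMM scoring against every family model, homology
## fallback for families without models, heme-motif counting, the special
## length/motif filters (the Cyc2 rule is the data-driven instance), and
## best-hit resolution into one primary annotation per gene with all
## passing secondary hits retained for the neighborhood rules.

#' Count canonical c-type heme-binding motifs
#'
#' Non-overlapping occurrences of the canonical CxxCH motif, scanned left
#' to right. Only the canonical spacing is counted (no CxxxCH/CxxxxCH
#' variants).
#'
#' @param protein amino-acid string (non-empty).
#' @return Non-negative integer motif count.
#' @export
#' @examples
#' countHemeMotifs("CAACHGGCAACH")  # 2
countHemeMotifs <- function(protein) {
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  m <- gregexpr("C..CH", toupper(protein), perl = TRUE)[[1]]
  sum(m > 0)
}

#' Cyc2 acceptance filter
#'
#' A candidate that passed its bit cutoff is accepted as Cyc2 only when
#' the protein carries at least one canonical heme-binding motif and is
#' at least 375 amino acids long (long enough to encode the fused outer
#' membrane porin domain).
#'
#' @param candidate a score list from \code{\link{viterbiBits}} (must
#'   have passed its cutoff).
#' @param protein the candidate's amino-acid sequence.
#' @param minLength minimum accepted length (amino acids).
#' @param minMotifs minimum heme-motif count.
#' @return TRUE iff the candidate is accepted.
#' @export
cyc2Accept <- function(candidate, protein, minLength = 375, minMotifs = 1) {
  isTRUE(candidate$passed) &&
    nchar(protein) >= minLength &&
    countHemeMotifs(protein) >= minMotifs
}

#' Resolve all passing hits of one gene into a primary annotation
#'
#' The primary hit is the one with the greatest margin; ties prefer the
#' hmm method over homology, remaining ties the lexicographically
#' smallest family id. All other passing hits are kept as secondaries.
#'
#' @param hits data.frame with at least \code{family_id}, \code{method},
#'   \code{margin} (one row per passing hit of a single gene).
#' @return \code{hits} reordered with a \code{role} column
#'   ("primary"/"secondary"); zero rows in, zero rows out.
#' @export
resolveBest <- function(hits) {
  hits$role <- character(nrow(hits))
  if (!nrow(hits)) return(hits)
  methodRank <- ifelse(hits$method == "hmm", 0L, 1L)
  o <- order(-hits$margin, methodRank, hits$family_id)
  hits <- hits[o, , drop = FALSE]
  hits$role <- c("primary", rep("secondary", nrow(hits) - 1L))
  rownames(hits) <- NULL
  hits
}

#' Annotate every gene of a sample against the family database
#'
#' Scores all genes against all hmm-family models (retaining scores at or
#' above each family's calibrated bit cutoff), runs the homology fallback
#' for homology-method families, applies the per-family minimum length
#' and heme-motif filters from the manifest, and resolves the passing
#' hits of each gene into one primary annotation plus retained
#' secondaries. Margins are score minus cutoff in bits for hmm hits and
#' log10(cutoff / e-value) for homology hits; both are >= 0 for every
#' retained annotation.
#'
#' @param genes a \code{\link{GeneCalls}} object.
#' @param db an \code{\link{IronFamilyDb}}.
#' @return data.frame with one row per retained (gene, family) hit,
#'   columns \code{gene_id}, \code{contig_id}, \code{index},
#'   \code{family_id}, \code{category}, \code{method}, \code{score},
#'   \code{cutoff}, \code{margin}, \code{heme_motifs}, \code{length},
#'   \code{role}, \code{flags}; ordered by (contig, index, role). The
#'   sample id is attached as attribute \code{"sample_id"}.
#' @export
annotateSample <- function(genes, db) {
  fam <- familyTable(db)
  tab <- geneTable(genes)
  aa <- as.character(proteins(genes))
  empty <- data.frame(gene_id = character(), contig_id = character(),
                      index = integer(), family_id = character(),
                      category = character(), method = character(),
                      score = numeric(), cutoff = numeric(),
                      margin = numeric(), heme_motifs = integer(),
                      length = integer(), role = character(),
                      flags = character(), stringsAsFactors = FALSE)
  if (!nrow(tab)) {
    warning("sample '", sampleId(genes), "' has no gene calls")
    attr(empty, "sample_id") <- sampleId(genes)
    return(empty)
  }
  motifs <- vapply(aa, countHemeMotifs, integer(1), USE.NAMES = FALSE)
  lens <- nchar(aa)
  hmmHits <- bestScores(familyModels(db), genes)
  rows <- list()
  for (g in seq_len(nrow(tab))) {
    h <- hmmHits[[g]]
    if (!nrow(h)) next
    fi <- match(h$model, fam$family_id)
    keepLen <- is.na(fam$min_length[fi]) | lens[g] >= fam$min_length[fi]
    keepHeme <- is.na(fam$min_heme_motifs[fi]) |
      motifs[g] >= fam$min_heme_motifs[fi]
    h <- h[keepLen & keepHeme, , drop = FALSE]
    if (!nrow(h)) next
    fi <- match(h$model, fam$family_id)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = tab$gene_id[g], contig_id = tab$contig_id[g],
      index = tab$index[g], family_id = h$model,
      category = fam$category[fi], method = "hmm", score = h$bits,
      cutoff = h$cutoff, margin = h$margin,
      heme_motifs = motifs[g], length = lens[g], role = "",
      flags = "", stringsAsFactors = FALSE)
  }
  for (f in fam$family_id[fam$method == "homology"]) {
    hits <- fallbackSearch(genes, db, f)
    if (!nrow(hits)) next
    gi <- match(hits$gene_id, tab$gene_id)
    fi <- match(f, fam$family_id)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = hits$gene_id, contig_id = tab$contig_id[gi],
      index = tab$index[gi], family_id = f,
      category = fam$category[fi], method = "homology",
      score = hits$evalue, cutoff = fam$cutoff[fi],
      margin = log10(fam$cutoff[fi] / hits$evalue),
      heme_motifs = motifs[gi], length = lens[gi], role = "",
      flags = "fallback_hit", stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    attr(empty, "sample_id") <- sampleId(genes)
    return(empty)
  }
  ann <- do.call(rbind, rows)
  ann <- do.call(rbind, lapply(split(ann, ann$gene_id), resolveBest))
  o <- order(ann$contig_id, ann$index, ann$role != "primary", ann$family_id)
  ann <- ann[o, , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "sample_id") <- sampleId(genes)
  ann
}

#' Write per-gene annotations as CSV (pipeline output 1)
#'
#' @param ann annotation data.frame from \code{\link{annotateSample}}.
#' @param genes the matching \code{\link{GeneCalls}} (for the protein
#'   sequences).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(ann, genes, path) {
  seqs <- as.character(proteins(genes))[match(ann$gene_id,
                                              geneTable(genes)$gene_id)]
  out <- cbind(sample = attr(ann, "sample_id"), ann,
               protein_sequence = seqs)
  utils::write.table(out, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}
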