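## Deterministic synthetic fixtures: toy profile HMMs, proteins emitted
## from them, and whole synthetic samples with planted iron-gene operons
## plus the truth labels and category calls the pipeline must recover.
## Everything is a pure function of the supplied seed.

#' Build a toy profile HMM around a consensus sequence
#'
#' Match state i emits \code{consensus[i]} with probability
#' \code{matchProb} and every other residue uniformly; insert states emit
#' the background; transitions heavily favor match-to-match (0.9).
#'
#' @param consensus amino-acid consensus string (length >= 1).
#' @param matchProb dominant emission probability, in (0.5, 1].
#' @param seed unused (construction is deterministic); accepted for
#'   interface symmetry with the other generators.
#' @return A valid \code{\link{ProfileHMM}} named after the consensus.
#' @export
makeToyHmm <- function(consensus, matchProb = 0.95, seed = NULL) {
  if (matchProb <= 0.5 || matchProb > 1)
    stop("matchProb must be in (0.5, 1]", call. = FALSE)
  res <- strsplit(toupper(consensus), "")[[1]]
  if (!length(res) || !all(res %in% AMINO))
    stop("consensus must be a non-empty string over the 20 amino acids",
         call. = FALSE)
  M <- length(res)
  me <- matrix((1 - matchProb) / 19, M, 20)
  me[cbind(seq_len(M), match(res, AMINO))] <- matchProb
  ProfileHMM(paste0("toy_", consensus), me)
}

#' Emit protein sequences from a profile HMM's generative path
#'
#' Sequences are sampled by walking the model from match state 1 to the
#' final node, emitting match and insert residues according to the model
#' probabilities. Reproducible for a fixed seed.
#'
#' @param hmm a \code{\link{ProfileHMM}}.
#' @param n number of sequences (>= 1).
#' @param seed integer seed.
#' @return Character vector of \code{n} proteins.
#' @export
emitProteins <- function(hmm, n, seed = 1) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  withSeed(seed, vapply(seq_len(n), function(k) .emitOne(hmm), character(1)))
}

.emitOne <- function(hmm) {
  out <- character(0)
  i <- 1L
  state <- "M"
  repeat {
    if (state == "M") {
      out <- c(out, sample(AMINO, 1, prob = hmm@matchEmit[i, ]))
      if (i == hmm@M) break
      nxt <- sample(c("M", "I", "D"), 1, prob = hmm@transitions[i, 1:3])
    } else if (state == "I") {
      out <- c(out, sample(AMINO, 1, prob = hmm@insertEmit[i, ]))
      nxt <- sample(c("M", "I"), 1, prob = hmm@transitions[i, 4:5])
    } else {
      if (i == hmm@M) break
      nxt <- sample(c("M", "D"), 1, prob = hmm@transitions[i, 6:7])
    }
    if (state == "I" && nxt == "I") { state <- "I"; next }
    if (nxt == "I") { state <- "I"; next }
    i <- i + 1L
    state <- nxt
  }
  paste(out, collapse = "")
}

# residues that can never take part in a CxxCH motif
.MOTIF_FREE <- setdiff(AMINO, c("C", "H"))

.randomBackgroundProtein <- function(lenRange) {
  len <- sample(seq(lenRange[1], lenRange[2]), 1)
  paste(sample(AMINO, len, replace = TRUE), collapse = "")
}

# remove every CxxCH occurrence except one starting at `keepAt` (NULL: all)
.stripExtraMotifs <- function(s, keepAt = NULL) {
  repeat {
    m <- gregexpr("C..CH", s, perl = TRUE)[[1]]
    pos <- m[m > 0]
    if (!is.null(keepAt)) pos <- setdiff(pos, keepAt)
    if (!length(pos)) return(s)
    substr(s, pos[1], pos[1]) <- "A"
  }
}

# synthesize one planted gene for a family: an emission from its model
# (or a reference copy for homology families), padded and motif-enforced
# per the family's special filters
.plantProtein <- function(db, family, seed) {
  fam <- familyTable(db)
  i <- match(family, fam$family_id)
  if (is.na(i)) stop("family '", family, "' not in database", call. = FALSE)
  if (fam$method[i] == "homology")
    return(as.character(refSet(db, family)[[1]]))
  prot <- emitProteins(familyModels(db)[[family]], 1, seed = seed)
  minHeme <- fam$min_heme_motifs[i]
  if (!is.na(minHeme) && minHeme > 0 && nchar(prot) >= 7)
    substr(prot, 3, 7) <- "CAACH"  # guarantee the canonical motif survives
  minLen <- fam$min_length[i]
  if (!is.na(minLen) && nchar(prot) < minLen + 10) {
    pad <- withSeed(seed + 1L,
                    sample(.MOTIF_FREE, minLen + 15 - nchar(prot),
                           replace = TRUE))
    prot <- paste0(prot, paste(pad, collapse = ""))
  }
  prot
}

#' Synthetic length-controlled Cyc2-like candidate
#'
#' Builds a protein of exactly \code{length} residues that scores above
#' the named cyc2 model's bit cutoff and contains exactly one canonical
#' CxxCH heme-binding motif: an emission from the model with the motif
#' written in, padded with motif-incapable residues. Used to sweep the
#' length filter boundary.
#'
#' @param db an \code{\link{IronFamilyDb}} (default database).
#' @param length target protein length in amino acids.
#' @param seed integer seed.
#' @param family cyc2 family id (default \code{"cyc2_cluster1"}).
#' @return Protein string of the requested length.
#' @export
makeCyc2Candidate <- function(db, length, seed = 1,
                              family = "cyc2_cluster1") {
  core <- emitProteins(familyModels(db)[[family]], 1, seed = seed)
  if (nchar(core) >= 7) substr(core, 3, 7) <- "CAACH"
  core <- .stripExtraMotifs(core, keepAt = 3)
  if (nchar(core) > length) stop("length shorter than the model core",
                                 call. = FALSE)
  pad <- withSeed(seed + 1L,
                  sample(.MOTIF_FREE, length - nchar(core), replace = TRUE))
  paste0(core, paste(pad, collapse = ""))
}

#' Specify a synthetic sample with planted operons
#'
#' @param sampleId sample identifier.
#' @param seed integer seed; fully determines the generated sample.
#' @param nContigs number of contigs.
#' @param genesPerContig gene calls per contig.
#' @param planted list of planted gene groups, each a list with elements
#'   \code{contig} (1-based contig number), \code{at} (gene index of the
#'   first planted gene; members occupy consecutive indices) and
#'   \code{families} (character vector of family ids). Groups on the same
#'   contig must be separated by more than the neighborhood gap for the
#'   truth labels to hold.
#' @param lengthRange background protein length range in amino acids.
#' @return A \code{FixtureSpec} list.
#' @export
fixtureSpec <- function(sampleId, seed, nContigs = 2, genesPerContig = 12,
                        planted = list(), lengthRange = c(80, 450)) {
  for (g in planted) {
    if (g$contig > nContigs ||
        g$at + length(g$families) - 1 > genesPerContig)
      stop("planted group outside the contig gene range", call. = FALSE)
  }
  structure(list(sampleId = sampleId, seed = as.integer(seed),
                 nContigs = nContigs, genesPerContig = genesPerContig,
                 planted = planted, lengthRange = lengthRange),
            class = "FixtureSpec")
}

#' Build a synthetic sample and its truth set
#'
#' Writes a coordinate-header protein FASTA in which planted genes are
#' emissions from the named families' models (or reference copies for
#' homology families) and the remaining genes are i.i.d. background
#' draws, plus a JSON truth file. Returns the gene calls, per-gene truth
#' labels, and the exact category calls the rule engine must produce.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param db an \code{\link{IronFamilyDb}}.
#' @param dir output directory (created if needed).
#' @return List with elements \code{genes} (a \code{\link{GeneCalls}}),
#'   \code{labels} (data.frame gene_id/family_id), \code{expected}
#'   (data.frame of expected category calls), \code{faa} and \code{json}
#'   (file paths).
#' @export
buildFixture <- function(spec, db, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- familyTable(db)
  slot <- matrix(NA_character_, spec$nContigs, spec$genesPerContig)
  for (g in spec$planted) {
    idx <- g$at + seq_along(g$families) - 1
    if (any(!is.na(slot[g$contig, idx])))
      stop("planted groups overlap", call. = FALSE)
    slot[g$contig, idx] <- g$families
  }
  if (!all(is.na(slot)) && !all(stats::na.omit(c(slot)) %in% fam$family_id))
    stop("planted family not in the database", call. = FALSE)
  rows <- list(); seqs <- character()
  k <- 0L
  for (ci in seq_len(spec$nContigs)) {
    pos <- 1L
    for (gi in seq_len(spec$genesPerContig)) {
      k <- k + 1L
      famId <- slot[ci, gi]
      prot <- if (is.na(famId))
        withSeed(spec$seed * 1000L + k,
                 .randomBackgroundProtein(spec$lengthRange))
      else .plantProtein(db, famId, seed = spec$seed * 1000L + k)
      st <- pos
      en <- pos + 3L * nchar(prot) + 2L
      pos <- en + 51L
      rows[[k]] <- data.frame(
        gene_id = sprintf("c%d_%d", ci, gi),
        contig_id = sprintf("c%d", ci), index = gi,
        start = st, end = en, strand = "+", stringsAsFactors = FALSE)
      seqs <- c(seqs, prot)
    }
  }
  calls <- do.call(rbind, rows)
  genes <- GeneCalls(spec$sampleId, calls, seqs, orfCount = nrow(calls))
  faa <- file.path(dir, paste0(spec$sampleId, ".faa"))
  writeProteinCalls(genes, faa)
  labels <- data.frame(gene_id = calls$gene_id,
                       family_id = c(t(slot)), stringsAsFactors = FALSE)
  labels$family_id[is.na(labels$family_id)] <- "background"
  expected <- .expectedCalls(spec, db)
  json <- file.path(dir, paste0(spec$sampleId, ".truth.json"))
  jsonlite::write_json(list(sample = spec$sampleId, labels = labels,
                            expected = expected),
                       json, dataframe = "rows", auto_unbox = TRUE)
  list(genes = genes, labels = labels, expected = expected,
       faa = faa, json = json)
}

# truth-side evaluation of the shipped classification logic for one
# planted group; independent of the pipeline's neighborhood machinery
.expectedCalls <- function(spec, db) {
  fam <- familyTable(db)
  ru <- ruleTable(db)
  out <- list()
  emit <- function(contig, category, rule_id, genes, completeness = NA_real_) {
    out[[length(out) + 1]] <<- data.frame(
      sample_id = spec$sampleId, contig_id = contig, category = category,
      rule_id = rule_id,
      evidence_genes = paste(sort(genes), collapse = ","),
      completeness = completeness, stringsAsFactors = FALSE)
  }
  generic <- c("iron_transport", "heme_oxygenase", "heme_transport",
               "siderophore_transport", "iron_gene_regulation",
               "iron_storage")
  for (g in spec$planted) {
    contig <- sprintf("c%d", g$contig)
    gids <- sprintf("c%d_%d", g$contig, g$at + seq_along(g$families) - 1)
    fset <- unique(g$families)
    byFam <- split(gids, g$families)
    catOf <- fam$category[match(g$families, fam$family_id)]
    for (ri in seq_len(nrow(ru))) {
      req <- .csv(ru$required_families[ri])
      anyOf <- .csv(ru$any_of_families[ri])
      forb <- .csv(ru$forbidden_families[ri])
      if (length(req) && !all(req %in% fset)) next
      if (length(anyOf) && sum(anyOf %in% fset) < ru$min_any[ri]) next
      if (length(forb) && any(forb %in% fset)) next
      involved <- union(req, intersect(anyOf, fset))
      comp <- NA_real_
      if (!is.na(ru$operon_id[ri])) {
        mem <- operon(db, ru$operon_id[ri])$members
        comp <- length(intersect(mem, fset)) / length(mem)
      }
      emit(contig, ru$category[ri], ru$rule_id[ri],
           unlist(byFam[involved]), comp)
    }
    synth <- g$families[catOf == "siderophore_synthesis"]
    if (length(unique(synth)) >= 2)
      emit(contig, "siderophore_synthesis", "sid_synth_operon",
           unlist(byFam[unique(synth)]))
    else if (length(synth) == 1)
      emit(contig, "siderophore_synthesis", "sid_synth_single",
           unlist(byFam[synth]))
    for (j in seq_along(g$families))
      if (catOf[j] %in% generic)
        emit(contig, catOf[j], "gene_level", gids[j])
  }
  if (!length(out))
    return(data.frame(sample_id = character(), contig_id = character(),
                      category = character(), rule_id = character(),
                      evidence_genes = character(), completeness = numeric(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$contig_id, df$category, df$rule_id, df$evidence_genes), ]
  rownames(df) <- NULL
  df
}

.csv <- function(x) {
  if (is.na(x) || x == "-" || !nzchar(x)) character(0)
  else strsplit(x, ",")[[1]]
}

#' Default fixture suite specification for one seed
#'
#' A three-contig sample exercising the main rule families: a complete
#' mtrCAB operon plus a regulator, six of the ten mam markers plus a
#' ferritin-family gene, a cyc2 candidate, a lone mtoA, and a two-gene
#' siderophore synthesis cluster; all remaining genes are background.
#'
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @return A \code{\link{fixtureSpec}}.
#' @export
defaultFixtureSpec <- function(seed, sampleId = sprintf("synthetic_s%d", seed)) {
  fixtureSpec(
    sampleId, seed, nContigs = 3, genesPerContig = 14,
    planted = list(
      list(contig = 1, at = 3, families = c("mtrC", "mtrA", "mtrB")),
      list(contig = 1, at = 10, families = "fur"),
      list(contig = 2, at = 2,
           families = c("mamA", "mamB", "mamE", "mamK", "mamM", "mamO")),
      list(contig = 2, at = 12, families = "bfr"),
      list(contig = 3, at = 2, families = "cyc2_cluster1"),
      list(contig = 3, at = 8, families = "mtoA"),
      list(contig = 3, at = 12, families = c("iucA", "iucC"))))
}

#' @describeIn defaultFixtureSpec companion background-only sample (no
#'   planted genes; the pipeline must produce zero calls on it).
#' @export
backgroundFixtureSpec <- function(seed,
                                  sampleId = sprintf("background_s%d", seed)) {
  fixtureSpec(sampleId, seed + 500L, nContigs = 2, genesPerContig = 12)
}
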