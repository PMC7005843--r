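## Profile-HMM I/O (HMMER3 ASCII subset) and local Viterbi bit scoring.
##
## Scoring model: uni-local (Smith-Waterman-style) Viterbi in log2 space.
## An alignment enters at any match state with uniform probability 1/M
## (entry cost -log2(M) folded into the score), exits from any match state
## for free, and flanking residues are scored by the null model so they
## contribute 0 log-odds. No bias/null2 composition correction is applied:
## acceptance cutoffs are calibrated per model on this same scale.

.NLOG_STAR <- "*"  # zero probability in HMMER3 negative-natural-log fields

.fromNlog <- function(tok) {
  v <- suppressWarnings(as.numeric(tok))  # structural checks report errors
  ifelse(tok == .NLOG_STAR, 0, exp(-v))
}
.toNlog <- function(p) ifelse(p <= 0, .NLOG_STAR, sprintf("%.9f", -log(p)))

#' Parse profile HMMs from HMMER3 ASCII text
#'
#' Supports the plain-text subset written by \code{hmmbuild} and
#' \code{\link{writeHmmer3}}: header tags (\code{NAME}, \code{LENG},
#' \code{ALPH}), the optional \code{COMPO} background line, per-node
#' match/insert/transition lines and the \code{//} terminator. Negative
#' natural-log probability fields are converted to probabilities and
#' \code{"*"} parses as probability zero. Multiple concatenated models are
#' supported. When \code{COMPO} is absent the background is uniform 1/20.
#'
#' @param path path to a HMMER3 ASCII file, or \code{NULL} when
#'   \code{text} is given.
#' @param text character vector of lines (alternative to \code{path}).
#' @return A named list of \code{\link{ProfileHMM}} objects.
#' @export
parseHmmer3 <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  if (!length(lines) || !grepl("^HMMER3", lines[1]))
    stop("not a HMMER3 ASCII file (missing HMMER3 format tag)", call. = FALSE)
  starts <- grep("^HMMER3", lines)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts))
    stop("truncated HMMER3 file: missing '//' terminator", call. = FALSE)
  models <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    models[[k]] <- .parseOneHmm(block)
  }
  names(models) <- vapply(models, function(m) m@name, character(1))
  models
}

.parseOneHmm <- function(block) {
  tag <- function(t) {
    at <- grep(paste0("^", t, "\\s"), block)
    if (!length(at)) return(NA_character_)
    trimws(sub(paste0("^", t, "\\s+"), "", block[at[1]]))
  }
  alph <- tag("ALPH")
  if (is.na(alph) || tolower(alph) != "amino")
    stop("unsupported alphabet '", alph, "': only amino models are supported",
         call. = FALSE)
  nm <- tag("NAME"); if (is.na(nm)) nm <- "unnamed"
  M <- as.integer(tag("LENG"))
  hmmAt <- grep("^HMM\\s", block)
  if (!length(hmmAt) || is.na(M))
    stop("malformed HMMER3 model '", nm, "'", call. = FALSE)
  body <- block[(hmmAt + 2):length(block)]  # skip HMM + transition header
  body <- body[nzchar(trimws(body)) & !startsWith(trimws(body), "//")]
  toks <- lapply(body, function(l) strsplit(trimws(l), "\\s+")[[1]])
  bg <- rep(1 / 20, 20)
  i <- 1
  if (toks[[1]][1] == "COMPO") {
    bg <- .fromNlog(toks[[1]][2:21])
    bg <- bg / sum(bg)
    i <- 2
  }
  i <- i + 2  # node-0 insert emission and transition lines (unused: local entry)
  me <- matrix(0, M, 20); ie <- matrix(0, M, 20); tr <- matrix(0, M, 7)
  for (node in seq_len(M)) {
    if (i + 2 > length(toks))
      stop("truncated model '", nm, "': expected ", M, " nodes", call. = FALSE)
    mt <- toks[[i]]
    if (suppressWarnings(as.integer(mt[1])) != node)
      stop("malformed node line in model '", nm, "' (node ", node, ")",
           call. = FALSE)
    me[node, ] <- .fromNlog(mt[2:21])
    ie[node, ] <- .fromNlog(toks[[i + 1]][1:20])
    tr[node, ] <- .fromNlog(toks[[i + 2]][1:7])
    i <- i + 3
  }
  # renormalize away the finite-precision of the text encoding
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  tr[, 1:3] <- tr[, 1:3] / rowSums(tr[, 1:3, drop = FALSE])
  tr[, 4:5] <- tr[, 4:5] / rowSums(tr[, 4:5, drop = FALSE])
  ds <- rowSums(tr[, 6:7, drop = FALSE])
  tr[, 6:7] <- tr[, 6:7] / ifelse(ds > 0, ds, 1)
  tr[ds == 0, 6] <- 1
  ProfileHMM(nm, me, ie, tr, bg)
}

#' Write profile HMMs in HMMER3 ASCII format
#'
#' Emits the subset of the format read back by \code{\link{parseHmmer3}}
#' (header tags, COMPO background, node lines, terminator), with
#' probabilities encoded as negative natural logs at 9 decimal places.
#'
#' @param hmms a \code{\link{ProfileHMM}} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHmmer3 <- function(hmms, path) {
  if (is(hmms, "ProfileHMM")) hmms <- list(hmms)
  con <- file(path, "w"); on.exit(close(con))
  for (h in hmms) {
    writeLines(c(
      "HMMER3/f [ironScan profile subset]",
      paste("NAME ", h@name),
      paste("LENG ", h@M),
      "ALPH  amino",
      paste0("HMM          ", paste(sprintf("%8s", AMINO), collapse = " ")),
      paste("           ", paste(sprintf("%8s",
            c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")),
            collapse = " ")),
      paste("  COMPO  ", paste(sprintf("%12s", .toNlog(h@background)),
                               collapse = " ")),
      paste("         ", paste(sprintf("%12s", .toNlog(h@background)),
                               collapse = " ")),
      paste("         ", paste(sprintf("%12s",
            .toNlog(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1))), collapse = " "))
    ), con)
    for (i in seq_len(h@M)) {
      writeLines(c(
        paste(sprintf("%7d", i),
              paste(sprintf("%12s", .toNlog(h@matchEmit[i, ])), collapse = " ")),
        paste("       ",
              paste(sprintf("%12s", .toNlog(h@insertEmit[i, ])), collapse = " ")),
        paste("       ",
              paste(sprintf("%12s", .toNlog(h@transitions[i, ])), collapse = " "))
      ), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# per-model log2-odds matrices for the scoring kernel
.modelLogOdds <- function(hmm) {
  bg <- hmm@background
  list(lom = log2(sweep(hmm@matchEmit, 2, bg, "/")),
       loi = log2(sweep(hmm@insertEmit, 2, bg, "/")),
       ltr = log2(hmm@transitions))
}

.encodeProtein <- function(protein) {
  res <- strsplit(toupper(protein), "")[[1]]
  match(res, AMINO, nomatch = 0L) - 1L  # -1 marks unknown (X, B, Z, U, O, ...)
}

#' Score a protein against a profile HMM (local Viterbi bits)
#'
#' Computes the maximum log2 likelihood ratio of the model versus the
#' background over all local alignments: uniform 1/M entry into any match
#' state, free exit from any match state, flanking residues scored by the
#' null model. Residues outside the 20-letter alphabet contribute 0
#' log-odds everywhere. The score is compared against the model's
#' calibrated bit cutoff when one is set.
#'
#' @param hmm a \code{\link{ProfileHMM}}.
#' @param protein amino-acid string (non-empty).
#' @param cutoff acceptance threshold in bits; defaults to the model's
#'   calibrated cutoff.
#' @return A list with elements \code{model}, \code{bits}, \code{cutoff},
#'   \code{passed}.
#' @export
viterbiBits <- function(hmm, protein, cutoff = bitCutoff(hmm)) {
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  lo <- .modelLogOdds(hmm)
  bits <- .viterbiBitsC(lo$lom, lo$loi, lo$ltr, .encodeProtein(protein))
  list(model = hmm@name, bits = bits, cutoff = cutoff,
       passed = !is.na(cutoff) && bits >= cutoff)
}

#' Score all genes of a sample against a model library
#'
#' Every gene is scored against every model; only scores at or above the
#' model's bit cutoff are retained. Per-gene results are sorted by margin
#' (score minus cutoff) in decreasing order, ties broken by model name.
#'
#' @param hmms named list of \code{\link{ProfileHMM}} objects with cutoffs
#'   set.
#' @param genes a \code{\link{GeneCalls}} object.
#' @return Named list (one entry per gene id, in gene-table order) of
#'   data.frames with columns \code{model}, \code{bits}, \code{cutoff},
#'   \code{margin}.
#' @export
bestScores <- function(hmms, genes) {
  if (!length(hmms)) stop("at least one model is required", call. = FALSE)
  los <- lapply(hmms, .modelLogOdds)
  cuts <- vapply(hmms, bitCutoff, numeric(1))
  nms <- vapply(hmms, function(h) h@name, character(1))
  seqs <- as.character(proteins(genes))
  out <- vector("list", length(seqs))
  names(out) <- geneTable(genes)$gene_id
  empty <- data.frame(model = character(), bits = numeric(),
                      cutoff = numeric(), margin = numeric(),
                      stringsAsFactors = FALSE)
  for (g in seq_along(seqs)) {
    enc <- .encodeProtein(seqs[g])
    bits <- vapply(los, function(lo)
      .viterbiBitsC(lo$lom, lo$loi, lo$ltr, enc), numeric(1))
    keep <- !is.na(cuts) & bits >= cuts
    if (!any(keep)) { out[[g]] <- empty; next }
    df <- data.frame(model = nms[keep], bits = bits[keep],
                     cutoff = cuts[keep], margin = bits[keep] - cuts[keep],
                     stringsAsFactors = FALSE)
    df <- df[order(-df$margin, df$model), , drop = FALSE]
    rownames(df) <- NULL
    out[[g]] <- df
  }
  out
}
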