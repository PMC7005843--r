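## Reading/writing of contigs, protein calls and GenBank records, and the
## seam to an external ORF caller. Coordinates are 1-based inclusive on the
## forward strand, the convention of the Prodigal header dialect.

# minimal structural scan so format errors can name a line number
.scanFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    stop("malformed FASTA in '", path, "': no records (line 1)", call. = FALSE)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA in '", path, "': sequence before any header (line ",
         first, ")", call. = FALSE)
  invisible(lines)
}

#' Read assembled contigs from a nucleotide FASTA file
#'
#' One record per header; sequences are uppercased. Empty sequences and
#' files with no records are rejected with an error naming the offending
#' line.
#'
#' @param path path to a nucleotide FASTA file.
#' @return A \code{DNAStringSet}; names are the contig ids.
#' @export
readContigs <- function(path) {
  lines <- .scanFasta(path)
  hdr <- which(startsWith(trimws(lines), ">"))
  ctg <- Biostrings::readDNAStringSet(path)
  ctg <- Biostrings::DNAStringSet(toupper(as.character(ctg)))
  names(ctg) <- sub("\\s.*$", "", names(ctg))
  if (any(Biostrings::width(ctg) == 0)) {
    i <- which(Biostrings::width(ctg) == 0)[1]
    stop("malformed FASTA in '", path, "': empty sequence for record ",
         sQuote(names(ctg)[i]), " (line ", hdr[i], ")", call. = FALSE)
  }
  if (anyDuplicated(names(ctg)))
    stop("duplicate contig id in '", path, "'", call. = FALSE)
  ctg
}

.parseCoordHeader <- function(header) {
  # ">id # start # end # strand # attrs" (Prodigal dialect), or plain ">id"
  parts <- strsplit(header, "\\s*#\\s*")[[1]]
  id <- sub("\\s.*$", "", trimws(parts[1]))
  if (length(parts) < 4)
    return(list(id = id, start = NA_integer_, end = NA_integer_,
                strand = NA_character_, plain = TRUE))
  st <- suppressWarnings(as.integer(parts[2]))
  en <- suppressWarnings(as.integer(parts[3]))
  if (is.na(st) || is.na(en) ||
      parts[2] != as.character(st) || parts[3] != as.character(en))
    stop("non-integer coordinates in header '", header, "'", call. = FALSE)
  if (st > en)
    stop("start > end in header '", header, "'", call. = FALSE)
  strand <- if (trimws(parts[4]) %in% c("-1", "-")) "-" else "+"
  list(id = id, start = st, end = en, strand = strand, plain = FALSE)
}

#' Read protein gene calls from a coordinate-header FASTA file
#'
#' Headers in the ORF-caller dialect \code{">id # start # end # strand #
#' ..."} are parsed into coordinates and an ordinal gene index per contig;
#' the contig id is the header id with its trailing \code{_N} ordinal
#' stripped. Plain headers are also accepted: each such gene lands on its
#' own singleton pseudo-contig, so multi-gene neighborhood rules cannot
#' fire (a warning is emitted).
#'
#' @param path path to a protein FASTA file.
#' @param sampleId sample identifier; defaults to the file name.
#' @return A \code{\link{GeneCalls}} object with \code{orfCount} equal to
#'   the number of records.
#' @export
readProteinCalls <- function(path, sampleId = basename(path)) {
  .scanFasta(path)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no records in '", path, "'", call. = FALSE)
  meta <- lapply(names(aa), .parseCoordHeader)
  plain <- vapply(meta, `[[`, logical(1), "plain")
  if (any(plain))
    warning("plain protein headers: neighborhoods collapse to single genes, ",
            "multi-gene rules cannot fire")
  id <- vapply(meta, `[[`, character(1), "id")
  contig <- ifelse(grepl("_[0-9]+$", id) & !plain, sub("_[0-9]+$", "", id), id)
  calls <- data.frame(
    gene_id = id, contig_id = contig,
    index = NA_integer_,
    start = vapply(meta, `[[`, integer(1), "start"),
    end = vapply(meta, `[[`, integer(1), "end"),
    strand = vapply(meta, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  # ordinal index per contig: by start when known, else by file order
  for (ct in unique(calls$contig_id)) {
    sel <- which(calls$contig_id == ct)
    key <- calls$start[sel]
    o <- if (all(is.na(key))) seq_along(sel) else order(key)
    calls$index[sel[o]] <- seq_along(sel)
  }
  GeneCalls(sampleId, calls, aa, orfCount = length(aa))
}

#' Write gene calls as a coordinate-header protein FASTA file
#'
#' Inverse of \code{\link{readProteinCalls}} for coordinate-bearing calls:
#' re-reading the written file reproduces the gene table (gene ids must
#' follow the \code{contig_N} convention for the contig to round-trip).
#'
#' @param x a \code{\link{GeneCalls}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProteinCalls <- function(x, path) {
  cl <- geneTable(x)
  strand <- ifelse(is.na(cl$strand), "1", ifelse(cl$strand == "-", "-1", "1"))
  hdr <- ifelse(is.na(cl$start), cl$gene_id,
                sprintf("%s # %d # %d # %s # ID=%s", cl$gene_id, cl$start,
                        cl$end, strand, cl$gene_id))
  out <- proteins(x)
  names(out) <- hdr
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read gene calls from a GenBank flat file
#'
#' Minimal parser for the GenBank flat format: LOCUS records are treated
#' as contigs and translated CDS features become gene calls, ordered by
#' start coordinate. CDS features without a \code{/translation} qualifier
#' are skipped with a warning. Only simple and \code{complement()}
#' locations (optionally inside \code{join()}) are interpreted; the
#' feature's span is the min..max of its coordinates.
#'
#' @param path path to a GenBank flat file.
#' @param sampleId sample identifier; defaults to the file name.
#' @return A \code{\link{GeneCalls}} object; \code{orfCount} is the total
#'   CDS count.
#' @export
readGenbankCalls <- function(path, sampleId = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locusAt <- which(startsWith(lines, "LOCUS"))
  if (!length(locusAt)) stop("not a GenBank flat file: ", path, call. = FALSE)
  rows <- list(); prots <- character(); nCDS <- 0L; nSkipped <- 0L
  for (li in seq_along(locusAt)) {
    from <- locusAt[li]
    to <- if (li < length(locusAt)) locusAt[li + 1] - 1 else length(lines)
    block <- lines[from:to]
    contig <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    featStart <- grep("^FEATURES", block)
    if (!length(featStart)) next
    body <- block[(featStart + 1):length(block)]
    stopAt <- grep("^(ORIGIN|//|CONTIG)", body)
    if (length(stopAt)) body <- body[seq_len(stopAt[1] - 1)]
    isFeat <- grepl("^ {5}\\S", body)
    featAt <- which(isFeat)
    for (fi in seq_along(featAt)) {
      key <- strsplit(trimws(body[featAt[fi]]), "\\s+")[[1]][1]
      if (key != "CDS") next
      nCDS <- nCDS + 1L
      fTo <- if (fi < length(featAt)) featAt[fi + 1] - 1 else length(body)
      feat <- body[featAt[fi]:fTo]
      loctxt <- sub("^ {5}CDS\\s+", "", feat[1])
      qualAt <- grep("^ {21}/", feat)
      if (length(qualAt) && qualAt[1] > 2)
        loctxt <- paste0(loctxt, trimws(feat[2:(qualAt[1] - 1)]), collapse = "")
      strand <- if (grepl("complement", loctxt)) "-" else "+"
      coords <- as.integer(unlist(regmatches(loctxt, gregexpr("[0-9]+", loctxt))))
      tr <- .gbQualifier(feat, "translation")
      if (is.na(tr)) { nSkipped <- nSkipped + 1L; next }
      gid <- .gbQualifier(feat, "locus_tag")
      if (is.na(gid)) gid <- .gbQualifier(feat, "protein_id")
      if (is.na(gid)) gid <- sprintf("%s_CDS%d", contig, nCDS)
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gid, contig_id = contig, index = NA_integer_,
        start = min(coords), end = max(coords), strand = strand,
        stringsAsFactors = FALSE)
      prots <- c(prots, tr)
    }
  }
  if (nCDS == 0L)
    stop("no protein-coding features in '", path, "'", call. = FALSE)
  if (nSkipped > 0L)
    warning(nSkipped, " CDS feature(s) without /translation skipped")
  if (!length(rows))
    stop("no translated protein-coding features in '", path, "'", call. = FALSE)
  calls <- do.call(rbind, rows)
  for (ct in unique(calls$contig_id)) {
    sel <- which(calls$contig_id == ct)
    calls$index[sel[order(calls$start[sel])]] <- seq_along(sel)
  }
  if (anyDuplicated(calls$gene_id))
    calls$gene_id <- make.unique(calls$gene_id, sep = "_dup")
  GeneCalls(sampleId, calls, prots, orfCount = nCDS)
}

.gbQualifier <- function(featLines, name) {
  at <- grep(sprintf("^ {21}/%s=", name), featLines)
  if (!length(at)) return(NA_character_)
  val <- sub(sprintf("^ {21}/%s=", name), "", featLines[at[1]])
  quoted <- startsWith(val, "\"")
  val <- gsub("\"", "", val)
  if (quoted && !endsWith(featLines[at[1]], "\"")) {
    j <- at[1] + 1
    while (j <= length(featLines) && !grepl("^ {21}/", featLines[j])) {
      seg <- trimws(featLines[j])
      done <- endsWith(seg, "\"")
      val <- paste0(val, gsub("\"", "", seg))
      if (done) break
      j <- j + 1
    }
  }
  val
}

#' Predict genes by invoking an external ORF caller
#'
#' Runs a Prodigal-compatible gene caller on assembled contigs and parses
#' its protein output through \code{\link{readProteinCalls}}. The tool is
#' invoked as \code{tool -i <contigs> -a <proteins> -p <mode> -q}.
#'
#' @param contigs a \code{DNAStringSet} of contigs (see
#'   \code{\link{readContigs}}).
#' @param tool name or path of the executable (default \code{"prodigal"}).
#' @param mode \code{"meta"} for metagenomes, \code{"single"} for isolate
#'   genomes.
#' @param sampleId sample identifier for the result.
#' @return A \code{\link{GeneCalls}} object. The tool name, version string
#'   and mode are attached as the \code{"provenance"} attribute.
#' @export
callGenesExternal <- function(contigs, tool = "prodigal",
                              mode = c("meta", "single"),
                              sampleId = "sample") {
  mode <- match.arg(mode)
  if (!length(contigs)) stop("no contigs supplied", call. = FALSE)
  exe <- Sys.which(tool)
  if (!nzchar(exe) && file.exists(tool)) exe <- tool
  if (!nzchar(exe))
    stop("ORF caller '", tool, "' not found on PATH; supply protein FASTA ",
         "(readProteinCalls) or GenBank (readGenbankCalls) input instead",
         call. = FALSE)
  fna <- tempfile(fileext = ".fna"); faa <- tempfile(fileext = ".faa")
  on.exit(unlink(c(fna, faa)), add = TRUE)
  Biostrings::writeXStringSet(contigs, fna)
  status <- suppressWarnings(
    system2(exe, c("-i", fna, "-a", faa, "-p", mode, "-q"),
            stdout = FALSE, stderr = FALSE))
  if (status != 0 || !file.exists(faa))
    stop("ORF caller '", tool, "' failed (exit status ", status, ")",
         call. = FALSE)
  gc <- readProteinCalls(faa, sampleId = sampleId)
  attr(gc, "provenance") <- list(tool = tool, path = unname(exe), mode = mode)
  gc
}
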