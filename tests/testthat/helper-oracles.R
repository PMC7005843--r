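# Shared fixtures and independent oracles for the test suite.

.cache <- new.env(parent = emptyenv())

# the default database is deterministic; build it once per test run
sharedDb <- function() {
  if (is.null(.cache$db)) .cache$db <- defaultDatabase()
  .cache$db
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Exhaustive path-enumeration oracle for the local Viterbi score:
# enumerates every local alignment (entry at any match state and start
# position, any M/I/D path, exit at any match state) and returns the
# maximum log2-odds score. Tractable for M <= 4, sequences <= 8.
enumViterbiBits <- function(hmm, protein) {
  res <- match(strsplit(toupper(protein), "")[[1]], AA20, nomatch = 0L) - 1L
  M <- modelLength(hmm)
  L <- length(res)
  bg <- hmm@background
  lom <- unname(log2(sweep(hmm@matchEmit, 2, bg, "/")))
  loi <- unname(log2(sweep(hmm@insertEmit, 2, bg, "/")))
  ltr <- unname(log2(hmm@transitions))
  emit <- function(mat, i, j) if (res[j] >= 0) unname(mat[i, res[j] + 1]) else 0
  best <- -Inf
  rec <- function(state, i, j, sc) {
    if (state == "M" && sc > best) best <<- sc
    if (state == "M") {
      if (i < M) {
        if (j < L) rec("M", i + 1, j + 1, sc + ltr[i, 1] + emit(lom, i + 1, j + 1))
        if (j < L) rec("I", i, j + 1, sc + ltr[i, 2] + emit(loi, i, j + 1))
        rec("D", i + 1, j, sc + ltr[i, 3])
      }
    } else if (state == "I") {
      if (i < M && j < L)
        rec("M", i + 1, j + 1, sc + ltr[i, 4] + emit(lom, i + 1, j + 1))
      if (j < L) rec("I", i, j + 1, sc + ltr[i, 5] + emit(loi, i, j + 1))
    } else {
      if (i < M) {
        if (j < L) rec("M", i + 1, j + 1, sc + ltr[i, 6] + emit(lom, i + 1, j + 1))
        rec("D", i + 1, j, sc + ltr[i, 7])
      }
    }
  }
  for (j0 in seq_len(L))
    for (s in seq_len(M))
      rec("M", s, j0, -log2(M) + emit(lom, s, j0))
  best
}

# Brute-force transitive-closure oracle for neighborhood construction:
# repeatedly merges index groups whenever any pair across them is within
# maxGap, then reports sorted component keys.
bruteComponents <- function(indices, maxGap) {
  if (!length(indices)) return(character(0))
  adj <- abs(outer(indices, indices, "-")) <= maxGap
  repeat {
    nxt <- (adj %*% adj > 0) | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  sort(unique(apply(adj, 1, function(r)
    paste(sort(indices[r]), collapse = ","))))
}

# minimal annotation table for driving the neighborhood/rule engine
# directly (one primary hmm annotation per (family, index) pair)
mkAnn <- function(families, indices, contig = "c1", sample = "s") {
  stopifnot(length(families) == length(indices))
  ann <- data.frame(
    gene_id = sprintf("%s_%d", contig, indices), contig_id = contig,
    index = as.integer(indices), family_id = families,
    category = familyTable(sharedDb())$category[
      match(families, familyTable(sharedDb())$family_id)],
    method = "hmm", score = 50, cutoff = 30, margin = 20,
    heme_motifs = 0L, length = 200L, role = "primary", flags = "",
    stringsAsFactors = FALSE)
  attr(ann, "sample_id") <- sample
  ann
}

# random toy models for the scoring oracle sweeps
randomToyModel <- function(seed, maxM = 4) {
  withSeed(seed, {
    M <- sample(maxM, 1)
    makeToyHmm(paste(sample(AA20, M, replace = TRUE), collapse = ""),
               matchProb = runif(1, 0.6, 0.95))
  })
}

randomPeptide <- function(seed, maxLen = 8) {
  withSeed(seed + 10000,
           paste(sample(AA20, sample(maxLen, 1), replace = TRUE),
                 collapse = ""))
}

withSeed <- ironScan:::withSeed
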