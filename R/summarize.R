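## Comparative summaries across samples: category-by-sample count
## matrices, ORF-normalized abundances, row scaling for heatmaps, and
## Ward/Euclidean hierarchical clustering with ordinary bootstrap
## support. All numeric file output is written at 6 significant digits.

#' Category-by-sample count matrix
#'
#' One row per functional category (fixed 12-row order), one column per
#' sample; each cell is the number of distinct evidence genes
#' contributing to calls of that category in that sample (a gene is
#' counted once per category, but may appear in several categories).
#'
#' @param results list of per-sample results from
#'   \code{\link{screenSample}} (each needs \code{sample_id} and
#'   \code{calls}).
#' @return Integer matrix, 12 x n_samples, with the per-sample ORF counts
#'   attached as attribute \code{"orf_counts"} when available.
#' @export
countMatrix <- function(results) {
  if (!length(results)) stop("at least one sample is required", call. = FALSE)
  ids <- vapply(results, `[[`, character(1), "sample_id")
  mat <- matrix(0L, nrow = 12, ncol = length(results),
                dimnames = list(categorySchema(), ids))
  for (j in seq_along(results)) {
    calls <- results[[j]]$calls
    if (!nrow(calls)) next
    for (cat in unique(calls$category)) {
      genes <- unique(unlist(strsplit(
        calls$evidence_genes[calls$category == cat], ",")))
      mat[cat, j] <- length(genes)
    }
  }
  orf <- vapply(results, function(r)
    if (!is.null(r$genes)) orfCount(r$genes) else NA_integer_, integer(1))
  attr(mat, "orf_counts") <- setNames(orf, ids)
  mat
}

#' Normalize counts to predicted ORFs
#'
#' Each cell becomes \code{100 * count / orf_count}: the percentage of a
#' sample's predicted protein-coding genes assigned to the category.
#'
#' @param mat matrix from \code{\link{countMatrix}}.
#' @param orfCounts named vector of per-sample ORF counts; defaults to
#'   the attribute attached by \code{countMatrix}.
#' @return Numeric matrix of the same shape.
#' @export
normalizeMatrix <- function(mat, orfCounts = attr(mat, "orf_counts")) {
  if (is.null(orfCounts) || any(is.na(orfCounts[colnames(mat)])))
    stop("missing orf_count for some sample", call. = FALSE)
  orfCounts <- orfCounts[colnames(mat)]
  if (any(orfCounts <= 0)) stop("orf_count must be positive", call. = FALSE)
  sweep(mat, 2, orfCounts, function(x, n) 100 * x / n)
}

#' Center and scale category rows (z-scores)
#'
#' Each row is centered to mean 0 and scaled to standard deviation 1
#' (sample sd, n - 1 denominator); all-constant rows map to all-zero.
#'
#' @param mat numeric matrix with >= 2 columns.
#' @return The row-scaled matrix.
#' @export
scaleRows <- function(mat) {
  if (ncol(mat) < 2)
    stop("row scaling is undefined for a single sample", call. = FALSE)
  out <- t(apply(mat, 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  dimnames(out) <- dimnames(mat)
  out
}

#' Ward/Euclidean hierarchical clustering with bootstrap support
#'
#' Agglomerates the sample columns by Ward's variance-minimizing method
#' on Euclidean distances (\code{hclust} method \code{"ward.D2"}).
#' Cluster uncertainty is assessed by an ordinary bootstrap: category
#' rows are resampled with replacement B times and each internal node's
#' support is the percentage of resampled trees containing the same leaf
#' set. The root's support is 100 by construction.
#'
#' @param mat numeric matrix (categories x samples, usually row-scaled);
#'   >= 2 samples.
#' @param seed integer seed driving the bootstrap resampling.
#' @param B number of bootstrap resamples (>= 0; 0 disables support).
#' @return List with \code{hclust} (the merge tree), \code{support}
#'   (named vector, one entry per internal node keyed by its sorted leaf
#'   set; NULL when B = 0 or support is undefined), \code{B}, and
#'   \code{method} metadata (linkage dialect, distance, row scaling
#'   convention).
#' @export
wardCluster <- function(mat, seed = 1, B = 100) {
  if (ncol(mat) < 2) stop("need >= 2 samples to cluster", call. = FALSE)
  hc <- stats::hclust(stats::dist(t(mat)), method = "ward.D2")
  support <- NULL
  if (B > 0 && ncol(mat) >= 3) {
    keys <- .mergeLeafSets(hc)
    hits <- setNames(numeric(length(keys)), keys)
    bootKeys <- withSeed(seed, lapply(seq_len(B), function(b) {
      rows <- sample(nrow(mat), nrow(mat), replace = TRUE)
      .mergeLeafSets(stats::hclust(stats::dist(t(mat[rows, , drop = FALSE])),
                                   method = "ward.D2"))
    }))
    for (bk in bootKeys) hits[keys %in% bk] <- hits[keys %in% bk] + 1
    support <- 100 * hits / B
  }
  list(hclust = hc, support = support, B = B,
       method = list(linkage = "ward.D2 (Lance-Williams on squared Euclidean)",
                     distance = "euclidean",
                     row_scaling = "sample sd (n-1)"))
}

# leaf-set key of every internal node of an hclust tree
.mergeLeafSets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    pick <- function(v) if (v < 0) hc$labels[-v] else sets[[v]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  vapply(sets, paste, character(1), collapse = "|")
}

#' Newick serialization of a clustered dendrogram
#'
#' Internal nodes are labelled with their bootstrap support (when
#' available) and branch lengths derive from the Ward merge heights.
#'
#' @param cl result of \code{\link{wardCluster}}.
#' @return Single Newick string (terminated by \code{";"}).
#' @export
dendrogramNewick <- function(cl) {
  hc <- cl$hclust
  n <- length(hc$labels)
  keys <- .mergeLeafSets(hc)
  lab <- function(i) {
    if (is.null(cl$support)) return("")
    format(signif(unname(cl$support[keys[i]]), 6))
  }
  h <- function(v) if (v < 0) 0 else hc$height[v]
  render <- function(v, parentHeight) {
    if (v < 0)
      sprintf("%s:%s", hc$labels[-v], format(signif(parentHeight, 6)))
    else
      sprintf("(%s,%s)%s:%s",
              render(hc$merge[v, 1], hc$height[v] - h(hc$merge[v, 1])),
              render(hc$merge[v, 2], hc$height[v] - h(hc$merge[v, 2])),
              lab(v), format(signif(parentHeight, 6)))
  }
  root <- n - 1
  paste0("(",
         render(hc$merge[root, 1], hc$height[root] - h(hc$merge[root, 1])),
         ",",
         render(hc$merge[root, 2], hc$height[root] - h(hc$merge[root, 2])),
         ")", lab(root), ";")
}

#' Export comparative summaries (pipeline outputs 2-3)
#'
#' Writes the category-by-sample matrix as TSV, a long-format dot-plot
#' table (sample, category, value), the dendrogram as Newick with
#' bootstrap support as internal node labels, and optionally a rendered
#' heatmap (requires the pheatmap package).
#'
#' @param mat matrix to export (counts or normalized values).
#' @param cl result of \code{\link{wardCluster}}, or NULL to skip the
#'   tree.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param figures render a heatmap PNG when pheatmap is available.
#' @return Named character vector of the files written, invisibly.
#' @export
exportSummaries <- function(mat, cl = NULL, dir = ".", prefix = "iron_genes",
                            figures = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  matPath <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  out <- data.frame(category = rownames(mat),
                    signif(unclass(mat), 6), check.names = FALSE)
  utils::write.table(out, matPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files["matrix"] <- matPath
  long <- data.frame(
    sample = rep(colnames(mat), each = nrow(mat)),
    category = rep(rownames(mat), ncol(mat)),
    value = signif(as.vector(mat), 6))
  dotPath <- file.path(dir, paste0(prefix, "_dotplot.tsv"))
  utils::write.table(long, dotPath, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files["dotplot"] <- dotPath
  if (!is.null(cl)) {
    nwk <- file.path(dir, paste0(prefix, "_dendrogram.nwk"))
    writeLines(dendrogramNewick(cl), nwk)
    files["newick"] <- nwk
    meta <- file.path(dir, paste0(prefix, "_clustering.json"))
    jsonlite::write_json(c(cl$method, list(bootstrap_B = cl$B)), meta,
                         auto_unbox = TRUE)
    files["metadata"] <- meta
  }
  if (figures && requireNamespace("pheatmap", quietly = TRUE)) {
    png <- file.path(dir, paste0(prefix, "_heatmap.png"))
    grDevices::png(png, width = 900, height = 700)
    pheatmap::pheatmap(mat, cluster_rows = FALSE,
                       clustering_method = "ward.D2")
    grDevices::dev.off()
    files["heatmap"] <- png
  }
  invisible(files)
}
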