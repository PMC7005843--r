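# lightweight stand-in for a screened sample
mkResult <- function(id, calls, orf = 1000L) {
  calls$sample_id <- rep(id, nrow(calls))
  genes <- GeneCalls(id,
                     data.frame(gene_id = paste0(id, "_g1"), contig_id = "c1",
                                index = 1L, start = NA_integer_,
                                end = NA_integer_, strand = NA_character_,
                                stringsAsFactors = FALSE),
                     "MKLV", orfCount = orf)
  list(sample_id = id, genes = genes, calls = calls)
}

mkCalls <- function(categories, genes) {
  n <- length(categories)
  data.frame(sample_id = rep("x", n), contig_id = rep("c1", n),
             category = categories, rule_id = rep("r", n),
             evidence_families = rep("f", n), evidence_genes = genes,
             completeness = rep(NA_real_, n), flags = rep("", n),
             stringsAsFactors = FALSE)
}

test_that("count matrix counts distinct evidence genes once per category", {
  r1 <- mkResult("s1", mkCalls(c("iron_reduction", "iron_reduction"),
                               c("g1,g2", "g2")))
  # one gene contributing to two categories counts once in each
  r2 <- mkResult("s2", mkCalls(c("iron_storage", "iron_transport"),
                               c("g9", "g9")))
  r3 <- mkResult("s3", mkCalls(character(0), character(0)))
  mat <- countMatrix(list(r1, r2, r3))
  expect_equal(dim(mat), c(12L, 3L))
  expect_equal(rownames(mat), categorySchema())
  expect_equal(mat["iron_reduction", "s1"], 2L)
  expect_equal(mat["iron_storage", "s2"], 1L)
  expect_equal(mat["iron_transport", "s2"], 1L)
  expect_true(all(mat[, "s3"] == 0))
})

test_that("normalization is 100 x count / predicted ORFs", {
  r1 <- mkResult("s1", mkCalls("iron_storage",
                               paste(paste0("g", 1:5), collapse = ",")),
                 orf = 1000L)
  r2 <- mkResult("s2", mkCalls("iron_storage",
                               paste(paste0("g", 1:5), collapse = ",")),
                 orf = 2000L)
  mat <- countMatrix(list(r1, r2))
  nm <- normalizeMatrix(mat)
  expect_equal(nm["iron_storage", "s1"], 0.5)
  # doubling the ORF count halves the normalized value
  expect_equal(nm["iron_storage", "s2"], 0.25)
  expect_equal(nm["iron_reduction", "s1"], 0)
  attr(mat, "orf_counts") <- NULL
  expect_error(normalizeMatrix(mat), "orf_count")
})

test_that("row scaling gives zero-mean unit-sd rows under sample sd", {
  m <- matrix(c(0, 10, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  z <- scaleRows(m)
  expect_equal(unname(z["a", ]), c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(unname(z["b", ]), c(0, 0))
  m3 <- matrix(rnorm(36), 6, 6)
  z3 <- scaleRows(m3)
  expect_true(all(abs(rowMeans(z3)) < 1e-12))
  expect_true(all(abs(apply(z3, 1, sd) - 1) < 1e-9))
  expect_error(scaleRows(m[, 1, drop = FALSE]), "single sample")
})

demoMatrix <- function() {
  set.seed(20)
  m <- matrix(rnorm(12 * 4), nrow = 12,
              dimnames = list(categorySchema(),
                              c("sampA", "sampB", "sampC", "sampD")))
  m[, "sampB"] <- m[, "sampA"] + rnorm(12, sd = 0.01)  # near-duplicate pair
  m
}

test_that("Ward clustering has monotone heights and pairs duplicates at zero", {
  m <- demoMatrix()
  m <- cbind(m, sampDup = m[, "sampA"])
  cl <- wardCluster(m, seed = 5, B = 50)
  hc <- cl$hclust
  expect_true(all(diff(hc$height) >= -1e-12))
  # exact duplicates merge first at height 0
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("sampA", "sampDup"))
  expect_equal(hc$height[1], 0)
})

test_that("cluster topology ignores sample order and bootstrap is seeded", {
  m <- demoMatrix()
  cl1 <- wardCluster(m, seed = 9, B = 80)
  perm <- c(3, 1, 4, 2)
  cl2 <- wardCluster(m[, perm], seed = 9, B = 80)
  key <- function(cl) sort(ironScan:::.mergeLeafSets(cl$hclust))
  expect_equal(key(cl1), key(cl2))
  # identical seed -> identical support; root supported by construction
  cl1b <- wardCluster(m, seed = 9, B = 80)
  expect_identical(cl1$support, cl1b$support)
  root <- paste(sort(colnames(m)), collapse = "|")
  expect_equal(unname(cl1$support[root]), 100)
  expect_true(all(cl1$support >= 0 & cl1$support <= 100))
  # support undefined below three samples
  expect_null(wardCluster(m[, 1:2], seed = 1, B = 10)$support)
})

test_that("exports round-trip through TSV and Newick", {
  skip_if_not_installed("ape")
  m <- demoMatrix()[, 1:3]
  cl <- wardCluster(m, seed = 2, B = 20)
  dir <- withr::local_tempdir()
  files <- exportSummaries(m, cl, dir = dir, prefix = "t")
  tsv <- read.delim(files[["matrix"]], check.names = FALSE)
  expect_equal(dim(tsv), c(12L, 4L))  # category column + 3 samples
  long <- read.delim(files[["dotplot"]])
  expect_equal(nrow(long), 36L)
  tree <- ape::read.tree(files[["newick"]])
  expect_equal(sort(tree$tip.label), sort(colnames(m)))
  # the Newick topology reproduces the merge tree
  expect_equal(sort(ape::prop.part(tree)[[1]]), 1:3)
  nwk1 <- dendrogramNewick(cl)
  expect_identical(nwk1, dendrogramNewick(cl))
})
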