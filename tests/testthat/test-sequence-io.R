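test_that("contig FASTA reading normalizes case and validates structure", {
  f <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">c1", "ACGT", ">c2", "GG"), f)
  ctg <- readContigs(f)
  expect_length(ctg, 2)
  expect_equal(unname(BiocGenerics::width(ctg)), c(4L, 2L))

  writeLines(c(">low", "acgt"), f)
  expect_equal(as.character(readContigs(f)[[1]]), "ACGT")

  writeLines(character(0), f)
  expect_error(readContigs(f), "no records")
  writeLines(c("ACGT", ">late"), f)
  expect_error(readContigs(f), "line 1")
})

test_that("coordinate headers parse into gene calls with per-contig indices", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">c1_1 # 3 # 302 # 1 # ID=1_1", "MKLV",
               ">c1_2 # 400 # 900 # -1 # ID=1_2", "MGGA"), f)
  gc <- readProteinCalls(f)
  tab <- geneTable(gc)
  expect_equal(tab$contig_id, c("c1", "c1"))
  expect_equal(tab$index, c(1L, 2L))
  expect_equal(tab$start, c(3L, 400L))
  expect_equal(tab$end, c(302L, 900L))
  expect_equal(tab$strand, c("+", "-"))
  expect_equal(orfCount(gc), 2L)
})

test_that("plain headers fall back to singleton pseudo-contigs with a warning", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">geneA", "MKLV", ">geneB", "MGGA"), f)
  expect_warning(gc <- readProteinCalls(f), "neighborhoods collapse")
  tab <- geneTable(gc)
  expect_equal(tab$contig_id, c("geneA", "geneB"))
  expect_equal(tab$index, c(1L, 1L))
  expect_true(all(is.na(tab$start)))
})

test_that("malformed coordinate headers are rejected", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">c1_1 # three # 302 # 1 #", "MKLV"), f)
  expect_error(readProteinCalls(f), "non-integer")
  writeLines(c(">c1_1 # 500 # 302 # 1 #", "MKLV"), f)
  expect_error(readProteinCalls(f), "start > end")
})

test_that("protein-call round trip preserves all gene fields", {
  calls <- data.frame(
    gene_id = c("c1_1", "c1_2", "c2_1"), contig_id = c("c1", "c1", "c2"),
    index = c(1L, 2L, 1L), start = c(3L, 500L, 10L),
    end = c(302L, 1000L, 400L), strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  gc <- GeneCalls("s1", calls, c("MKLV", "MGGA", "MPPS"))
  f <- withr::local_tempfile(fileext = ".faa")
  writeProteinCalls(gc, f)
  back <- readProteinCalls(f, sampleId = "s1")
  expect_equal(geneTable(back), geneTable(gc))
  expect_equal(as.character(proteins(back)), as.character(proteins(gc)))
})

test_that("gene indices form a start-ordered permutation per contig", {
  f <- withr::local_tempfile(fileext = ".faa")
  # file order deliberately scrambled relative to coordinates
  writeLines(c(">c1_2 # 900 # 1200 # 1 #", "MAAA",
               ">c1_1 # 5 # 400 # 1 #", "MBBB"), f)
  tab <- geneTable(readProteinCalls(f))
  expect_equal(tab$index[order(tab$start)], seq_len(nrow(tab)))
})

gbRecord <- function() {
  c("LOCUS       ctgA                 5000 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     source          1..5000",
    "     CDS             10..300",
    "                     /locus_tag=\"g1\"",
    "                     /translation=\"MKLVAAGG\"",
    "     CDS             complement(400..900)",
    "                     /locus_tag=\"g2\"",
    "                     /translation=\"MGGAPLLS",
    "                     TTKV\"",
    "     CDS             1000..1500",
    "                     /locus_tag=\"g3\"",
    "                     /translation=\"MPPSQR\"",
    "ORIGIN",
    "//")
}

test_that("GenBank CDS features become ordered gene calls", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbRecord(), f)
  gc <- readGenbankCalls(f)
  tab <- geneTable(gc)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$index, 1:3)
  expect_equal(tab$strand, c("+", "-", "+"))
  expect_equal(unname(as.character(proteins(gc))[2]), "MGGAPLLSTTKV")
  expect_equal(orfCount(gc), 3L)
})

test_that("GenBank parsing flags untranslated CDS and rejects empty records", {
  f <- withr::local_tempfile(fileext = ".gbk")
  rec <- gbRecord()
  rec <- append(rec, c("     CDS             2000..2300",
                       "                     /locus_tag=\"g4\""),
                after = 13)
  writeLines(rec, f)
  expect_warning(gc <- readGenbankCalls(f), "skipped")
  expect_equal(length(gc), 3L)
  expect_equal(orfCount(gc), 4L)  # skipped CDS still counts as predicted

  writeLines(c("LOCUS       empty                 100 bp",
               "FEATURES             Location/Qualifiers",
               "     source          1..100", "ORIGIN", "//"), f)
  expect_error(readGenbankCalls(f), "no protein-coding features")
})

test_that("external ORF caller contract is honored through a stub", {
  stub <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "while [ $# -gt 0 ]; do",
               "  if [ \"$1\" = '-a' ]; then out=$2; fi",
               "  shift", "done",
               "printf '>c1_1 # 1 # 90 # 1 #\\nMKLV\\n>c1_2 # 100 # 190 # 1 #\\nMGGA\\n' > $out"),
             stub)
  Sys.chmod(stub, "0755")
  ctg <- Biostrings::DNAStringSet(c(c1 = "ACGTACGT"))
  gc <- callGenesExternal(ctg, tool = stub)
  expect_equal(length(gc), 2L)
  expect_equal(attr(gc, "provenance")$tool, stub)

  expect_error(callGenesExternal(ctg, tool = "no_such_caller_xyz"),
               "protein FASTA")
  expect_error(callGenesExternal(Biostrings::DNAStringSet(), tool = stub),
               "no contigs")
})
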