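test_that("the shipped database exposes the fixed 12-category schema", {
  db <- sharedDb()
  expect_length(categorySchema(), 12)
  expect_false(anyDuplicated(categorySchema()) > 0)
  expect_identical(categories(db), categorySchema())
  expect_true(all(familyTable(db)$category %in% categorySchema()))
})

test_that("key family groups match the published library structure", {
  db <- sharedDb()
  fam <- familyTable(db)
  expect_equal(sum(grepl("^cyc2_cluster", fam$family_id)), 3)
  hemophores <- c("isdX1", "isdX2", "hasA", "hxuA", "rv0203")
  ht <- familiesInCategory(db, "heme_transport")
  expect_true(all(hemophores %in% ht$family_id))
  storage <- familiesInCategory(db, "iron_storage")$family_id
  expect_true(all(c("bfr", "dpsA", "ftn") %in% storage))
  # listing is stable and name-sorted
  expect_equal(ht$family_id, sort(ht$family_id))
  expect_error(familiesInCategory(db, "iron_magic"), "unknown category")
})

test_that("operon definitions carry the published membership and thresholds", {
  db <- sharedDb()
  mam <- operon(db, "mam")
  expect_length(mam$members, 10)
  expect_setequal(mam$members, c("mamA", "mamB", "mamE", "mamK", "mamL",
                                 "mamM", "mamO", "mamP", "mamQ", "mamI"))
  expect_equal(mam$min_fraction, 0.5)
  mtr <- operon(db, "mtrCAB")
  expect_setequal(mtr$members, c("mtrC", "mtrA", "mtrB"))
  expect_equal(mtr$min_fraction, 1.0)
  expect_equal(mtr$category_on_partial, "probable_iron_reduction")
  expect_error(operon(db, "nope"), "unknown operon")
})

writeTinyManifest <- function(dir, rows = NULL) {
  dir.create(dir, showWarnings = FALSE)
  if (is.null(rows))
    rows <- c("famX\tiron_storage\thmm\tfamX\t10\t-\t-\t-\tcustom",
              "famY\tiron_transport\thmm\tfamY\t10\t-\t-\topX\tcustom",
              "famZ\tiron_reduction\thomology\tfamZ\t1e-10\t-\t-\topX\tcustom")
  man <- file.path(dir, "families.tsv")
  writeLines(c(paste("family_id", "category", "method", "model_ref",
                     "cutoff", "min_length", "min_heme_motifs",
                     "operon_group", "source", sep = "\t"), rows), man)
  ops <- file.path(dir, "operons.tsv")
  writeLines(c("operon_id\tmember_families\tmin_fraction\tcategory_on_success\tcategory_on_partial",
               "opX\tfamY,famZ\t1.0\tiron_reduction\t-"), ops)
  ru <- file.path(dir, "rules.tsv")
  writeLines(c("rule_id\tcategory\trequired_families\tany_of_families\tmin_any\tforbidden_families\toperon_id\tscope",
               "opX\tiron_reduction\tfamY,famZ\t-\t0\t-\topX\tneighborhood"),
             ru)
  writeHmmer3(list(makeToyHmm("CCCCW"), makeToyHmm("WWWWC")),
              file.path(dir, "famX.hmm"))
  file.copy(file.path(dir, "famX.hmm"), file.path(dir, "famY.hmm"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(r1 = "MKLVAAGGPLWWTTKV")),
    file.path(dir, "famZ.faa"))
  list(manifest = man, operons = ops, rules = ru, dir = dir)
}

test_that("manifest loading validates and binds models to cutoffs", {
  p <- writeTinyManifest(withr::local_tempdir())
  db <- loadManifest(p$manifest, p$dir, p$operons, p$rules)
  expect_s4_class(db, "IronFamilyDb")
  expect_equal(bitCutoff(familyModels(db)$famX), 10)
  expect_length(refSet(db, "famZ"), 1)
  expect_equal(operon(db, "opX")$members, c("famY", "famZ"))
})

test_that("manifest validation rejects bad categories, duplicates, missing models", {
  d <- withr::local_tempdir()
  p <- writeTinyManifest(d, rows = c(
    "famX\tiron_magic\thmm\tfamX\t10\t-\t-\t-\tcustom",
    "famY\tiron_transport\thmm\tfamY\t10\t-\t-\topX\tcustom",
    "famZ\tiron_reduction\thomology\tfamZ\t1e-10\t-\t-\topX\tcustom"))
  expect_error(loadManifest(p$manifest, d, p$operons, p$rules),
               "unknown category")

  p <- writeTinyManifest(d, rows = c(
    "famX\tiron_storage\thmm\tfamX\t10\t-\t-\t-\tcustom",
    "famX\tiron_storage\thmm\tfamX\t10\t-\t-\t-\tcustom",
    "famY\tiron_transport\thmm\tfamY\t10\t-\t-\topX\tcustom",
    "famZ\tiron_reduction\thomology\tfamZ\t1e-10\t-\t-\topX\tcustom"))
  expect_error(loadManifest(p$manifest, d, p$operons, p$rules),
               "duplicate family_id")

  p <- writeTinyManifest(d)
  unlink(file.path(d, "famY.hmm"))
  expect_error(loadManifest(p$manifest, d, p$operons, p$rules),
               "missing model file")
})

test_that("manifest validation is order-independent", {
  d1 <- writeTinyManifest(withr::local_tempdir())
  rows <- c("famZ\tiron_reduction\thomology\tfamZ\t1e-10\t-\t-\topX\tcustom",
            "famX\tiron_storage\thmm\tfamX\t10\t-\t-\t-\tcustom",
            "famY\tiron_transport\thmm\tfamY\t10\t-\t-\topX\tcustom")
  d2 <- writeTinyManifest(withr::local_tempdir(), rows = rows)
  db1 <- loadManifest(d1$manifest, d1$dir, d1$operons, d1$rules)
  db2 <- loadManifest(d2$manifest, d2$dir, d2$operons, d2$rules)
  f1 <- familyTable(db1); f2 <- familyTable(db2)
  expect_equal(f1[order(f1$family_id), ], f2[order(f2$family_id), ],
               ignore_attr = TRUE)
})

test_that("every operon member and rule reference resolves to a family", {
  db <- sharedDb()
  fam <- familyTable(db)$family_id
  members <- unlist(strsplit(db@operons$member_families, ","))
  expect_true(all(members %in% fam))
  ru <- ruleTable(db)
  refs <- unlist(lapply(c(ru$required_families, ru$any_of_families,
                          ru$forbidden_families),
                        function(x) if (is.na(x)) NULL
                        else strsplit(x, ",")[[1]]))
  expect_true(all(refs %in% fam))
})
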