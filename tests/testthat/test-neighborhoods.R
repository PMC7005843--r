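test_that("neighborhoods are gap-limited connected components", {
  ann <- mkAnn(c("bfr", "ftn", "dpsA"), c(3, 4, 6))
  nbs <- buildNeighborhoods(ann, maxGap = 2)
  expect_length(nbs, 1)
  expect_equal(nbs[[1]]$indices, c(3, 4, 6))

  ann2 <- mkAnn(c("bfr", "ftn"), c(3, 10))
  nbs2 <- buildNeighborhoods(ann2, maxGap = 2)
  expect_length(nbs2, 2)
  expect_true(all(lengths(lapply(nbs2, `[[`, "indices")) == 1))

  perm <- withSeed(3, sample(nrow(ann)))
  shuffled <- ann[perm, ]
  attr(shuffled, "sample_id") <- "s"
  expect_equal(lapply(buildNeighborhoods(shuffled, 2), `[[`, "indices"),
               lapply(nbs, `[[`, "indices"))
  expect_error(buildNeighborhoods(ann, maxGap = 0), ">= 1")
})

test_that("components match the brute-force transitive closure", {
  for (s in 1:25) {
    idx <- withSeed(s, sort(sample(20, sample(3:12, 1))))
    ann <- mkAnn(rep("bfr", length(idx)), idx)
    gap <- withSeed(s + 100, sample(1:4, 1))
    got <- sort(vapply(buildNeighborhoods(ann, gap),
                       function(nb) paste(nb$indices, collapse = ","),
                       character(1)))
    expect_equal(got, bruteComponents(idx, gap),
                 label = sprintf("seed %d gap %d", s, gap))
  }
})

test_that("operon completeness is the fraction of distinct members present", {
  db <- sharedDb()
  mam <- operon(db, "mam")
  nb6 <- list(families = mam$members[1:6])
  nb5 <- list(families = mam$members[1:5])
  nb4 <- list(families = c(mam$members[1:4], "bfr"))
  expect_equal(operonCompleteness(nb6, mam), 0.6)
  expect_equal(operonCompleteness(nb5, mam), 0.5)
  expect_equal(operonCompleteness(nb4, mam), 0.4)
})

test_that("the magnetosome rule fires at 50 percent completeness and above", {
  db <- sharedDb()
  mam <- operon(db, "mam")$members
  for (k in c(4, 5, 6)) {
    calls <- applyRules(buildNeighborhoods(mkAnn(mam[1:k], seq_len(k)), 3),
                        db)
    hit <- calls[calls$category == "magnetosome_formation", ]
    if (k >= 5) {
      expect_equal(nrow(hit), 1)
      expect_equal(hit$completeness, k / 10)
    } else {
      expect_equal(nrow(hit), 0)
    }
  }
})

test_that("porin-cytochrome rules reproduce the validation truth table", {
  db <- sharedDb()
  evalOn <- function(families) {
    calls <- applyRules(
      buildNeighborhoods(mkAnn(families, seq_along(families)), 3), db)
    calls[, c("category", "rule_id")]
  }
  full <- evalOn(c("mtrC", "mtrA", "mtrB"))
  expect_equal(full$category, "iron_reduction")
  expect_equal(full$rule_id, "mtrCAB")

  partial <- evalOn(c("mtrA", "mtrB"))
  expect_equal(partial$category, "probable_iron_reduction")
  expect_equal(partial$rule_id, "mtrAB")

  lone <- evalOn("mtoA")
  expect_equal(lone$category,
               "possible_iron_oxidation_and_possible_iron_reduction")

  # the complete operon shadows its partial fallback: never both
  expect_false(any(full$rule_id %in% c("mtrAB", "mtrCB")))
  mtoTrio <- evalOn(c("mtoA", "mtoB", "mtrC"))
  expect_equal(mtoTrio$category, "probable_iron_reduction")
  expect_equal(mtoTrio$rule_id, "mtoAB_mtrC")
})

test_that("oxidation rules respect their co-location arities", {
  db <- sharedDb()
  evalCat <- function(families) {
    calls <- applyRules(
      buildNeighborhoods(mkAnn(families, seq_along(families)), 3), db)
    calls$rule_id
  }
  expect_true("foxABC" %in% evalCat(c("foxA", "foxB")))
  expect_false("foxABC" %in% evalCat("foxA"))
  expect_true("foxEYZ" %in% evalCat(c("foxE", "foxY")))
  expect_false("foxEYZ" %in% evalCat(c("foxY", "foxZ")))  # anchor foxE absent
  expect_true("pioAB" %in% evalCat(c("pioA", "pioB")))
  expect_false("pioAB" %in% evalCat("pioA"))
  expect_true("cyc2_cluster3" %in% evalCat("cyc2_cluster3"))
})

test_that("siderophore synthesis needs co-location for full confidence", {
  db <- sharedDb()
  both <- applyRules(buildNeighborhoods(
    mkAnn(c("iucA", "iucC"), c(1, 2)), 3), db)
  expect_equal(both$rule_id, "sid_synth_operon")
  expect_equal(both$flags, "")

  single <- applyRules(buildNeighborhoods(mkAnn("iucA", 1), 3), db)
  expect_equal(single$rule_id, "sid_synth_single")
  expect_equal(single$flags, "low_confidence")
})

test_that("rule evaluation is pure and rejects unknown families", {
  db <- sharedDb()
  ann <- mkAnn(c("mtrC", "mtrA", "mtrB", "fur"), c(1, 2, 3, 9))
  nbs <- buildNeighborhoods(ann, 3)
  c1 <- applyRules(nbs, db)
  c2 <- applyRules(nbs, db)
  expect_identical(c1, c2)
  badRules <- ruleTable(db)
  badRules$required_families[1] <- "not_a_family"
  expect_error(applyRules(nbs, db, rules = badRules), "unknown families")
})
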