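## The family database: manifest of protein families bound to detection
## models, functional categories, cutoffs, special filters (length / heme
## motifs), operon definitions and the classification ruleset.

#' IronFamilyDb: validated iron-gene family database
#'
#' Binds the family manifest (one row per protein family: category,
#' detection method, cutoff, optional length/heme-motif filters, operon
#' membership), operon definitions, classification rules, parsed profile
#' HMMs for hmm-method families, reference protein sets for
#' homology-method families, and the search configuration defaults.
#'
#' @slot families manifest data.frame (columns \code{family_id},
#'   \code{category}, \code{method}, \code{model_ref}, \code{cutoff},
#'   \code{min_length}, \code{min_heme_motifs}, \code{operon_group},
#'   \code{source}).
#' @slot operons operon definition data.frame (\code{operon_id},
#'   \code{member_families} comma list, \code{min_fraction},
#'   \code{category_on_success}, \code{category_on_partial}).
#' @slot rules classification rule data.frame (see
#'   \code{\link{applyRules}}).
#' @slot models named list of \code{\link{ProfileHMM}} for hmm families,
#'   cutoffs attached.
#' @slot refSets named list of \code{AAStringSet} reference sets for
#'   homology families.
#' @slot config list of search defaults (e-value cutoff, homolog filter
#'   and dereplication identities, neighborhood gap, alignment scoring).
#' @export
setClass("IronFamilyDb",
         slots = c(families = "data.frame", operons = "data.frame",
                   rules = "data.frame", models = "list",
                   refSets = "list", config = "list"))

setValidity("IronFamilyDb", function(object) {
  msg <- character()
  fam <- object@families
  if (anyDuplicated(fam$family_id))
    msg <- c(msg, paste("duplicate family_id:",
                        paste(unique(fam$family_id[duplicated(fam$family_id)]),
                              collapse = ", ")))
  bad <- setdiff(unique(fam$category), categorySchema())
  if (length(bad))
    msg <- c(msg, paste0("unknown category label(s): ",
                         paste(bad, collapse = ", "),
                         "; allowed: ", paste(categorySchema(), collapse = ", ")))
  if (!all(fam$method %in% c("hmm", "homology")))
    msg <- c(msg, "method must be 'hmm' or 'homology'")
  hm <- fam$family_id[fam$method == "hmm"]
  if (!all(hm %in% names(object@models)))
    msg <- c(msg, paste("hmm families without a parsed model:",
                        paste(setdiff(hm, names(object@models)), collapse = ", ")))
  ho <- fam$family_id[fam$method == "homology"]
  if (!all(ho %in% names(object@refSets)))
    msg <- c(msg, paste("homology families without a reference set:",
                        paste(setdiff(ho, names(object@refSets)), collapse = ", ")))
  if (nrow(object@operons)) {
    mem <- strsplit(object@operons$member_families, ",")
    nmem <- lengths(mem)
    if (any(nmem < 2)) msg <- c(msg, "operons must have at least 2 members")
    mf <- object@operons$min_fraction
    if (any(mf <= 0 | mf > 1)) msg <- c(msg, "min_fraction must be in (0, 1]")
    missing <- setdiff(unlist(mem), fam$family_id)
    if (length(missing))
      msg <- c(msg, paste("operon member families not in manifest:",
                          paste(missing, collapse = ", ")))
  }
  if (nrow(object@rules)) {
    used <- unlist(c(strsplit(.orDash(object@rules$required_families), ","),
                     strsplit(.orDash(object@rules$any_of_families), ","),
                     strsplit(.orDash(object@rules$forbidden_families), ",")))
    missing <- setdiff(used, fam$family_id)
    if (length(missing))
      msg <- c(msg, paste("rule references unknown families:",
                          paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

.orDash <- function(x) { x[is.na(x) | x == "-"] <- ""; x }

.defaultConfig <- function() {
  list(
    evalue_cutoff = 1e-10,      # homology fallback acceptance threshold
    min_identity = 35,          # homolog gathering: % amino acid identity
    min_coverage = 0.7,         # homolog gathering: fraction of query aligned
    derep_identity = 70,        # dereplication: % identity collapse threshold
    max_gap = 3,                # neighborhood: max intervening gene indices
    substitution_matrix = "BLOSUM62",
    gap_open = 11, gap_extend = 1,
    # gapped Karlin-Altschul constants for BLOSUM62/11/1 (bits from raw score)
    lambda = 0.267, K = 0.041)
}

#' Search and classification defaults
#'
#' The default configuration attached to every database: homology
#' fallback e-value cutoff (1e-10), homolog gathering thresholds (35\%
#' identity over at least 70\% of the query), dereplication identity
#' (70\%), neighborhood gap (3 intervening gene indices), and the
#' alignment scoring constants (BLOSUM62, gap open 11 / extend 1, gapped
#' Karlin-Altschul lambda and K for the bit-score conversion).
#'
#' @return Named list of defaults.
#' @export
ironScanDefaults <- function() .defaultConfig()

.readManifestTable <- function(path) {
  fam <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "-", "NA"))
  need <- c("family_id", "category", "method", "model_ref", "cutoff",
            "min_length", "min_heme_motifs", "operon_group", "source")
  if (!all(need %in% names(fam)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  fam$cutoff <- as.numeric(fam$cutoff)
  fam$min_length <- as.integer(fam$min_length)
  fam$min_heme_motifs <- as.integer(fam$min_heme_motifs)
  fam
}

.readOperonTable <- function(path) {
  op <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "-", "NA"))
  op$min_fraction <- as.numeric(op$min_fraction)
  op
}

.readRuleTable <- function(path) {
  ru <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "-", "NA"))
  ru$min_any <- as.integer(ru$min_any)
  bad <- setdiff(unique(ru$category), categorySchema())
  if (length(bad))
    stop("ruleset uses unknown categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ru
}

#' Load and validate a family manifest with its model directory
#'
#' Reads the tab-separated family manifest, the operon definitions and the
#' classification ruleset, parses every referenced profile HMM
#' (\code{<model_ref>.hmm}, HMMER3 ASCII) and reference protein set
#' (\code{<model_ref>.faa}) from \code{modelDir}, attaches cutoffs to the
#' models, and validates the whole database: category labels must come
#' from \code{\link{categorySchema}}, family ids must be unique, every
#' operon member and rule reference must resolve to a manifest family.
#'
#' @param manifest path to the family manifest TSV.
#' @param modelDir directory holding the HMM and reference FASTA files.
#' @param operons path to the operon definition TSV.
#' @param rules path to the classification ruleset TSV.
#' @param config configuration list; see \code{\link{ironScanDefaults}}.
#' @return A validated \code{\link{IronFamilyDb}}.
#' @export
loadManifest <- function(manifest, modelDir, operons, rules,
                         config = ironScanDefaults()) {
  fam <- .readManifestTable(manifest)
  op <- .readOperonTable(operons)
  ru <- .readRuleTable(rules)
  models <- list(); refSets <- list()
  for (i in seq_len(nrow(fam))) {
    ref <- fam$model_ref[i]
    if (fam$method[i] == "hmm") {
      f <- file.path(modelDir, paste0(ref, ".hmm"))
      if (!file.exists(f))
        stop("family '", fam$family_id[i], "' references missing model file ",
             f, call. = FALSE)
      h <- parseHmmer3(f)[[1]]
      bitCutoff(h) <- fam$cutoff[i]
      models[[fam$family_id[i]]] <- h
    } else {
      f <- file.path(modelDir, paste0(ref, ".faa"))
      if (!file.exists(f))
        stop("family '", fam$family_id[i], "' references missing reference ",
             "FASTA ", f, call. = FALSE)
      refSets[[fam$family_id[i]]] <- Biostrings::readAAStringSet(f)
    }
  }
  db <- new("IronFamilyDb", families = fam, operons = op, rules = ru,
            models = models, refSets = refSets, config = config)
  validObject(db)
  db
}

# deterministic 32-bit seed from a family id (used for synthetic models)
.idSeed <- function(id, salt = 0L) {
  v <- utf8ToInt(id)
  h <- salt
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

#' The shipped default database (synthetic toy models)
#'
#' Loads the family manifest, operon definitions and ruleset shipped with
#' the package: a faithful skeleton of the published family/category/
#' operon structure. The profile HMMs and homology reference sets bound
#' to it are synthetic toy models generated deterministically from each
#' family id (consensus length 30, dominant match emission 0.95); they
#' stand in for the curated model library, which users mount via
#' \code{\link{loadManifest}}. Families with a heme-motif requirement get
#' a CxxCH motif written into their consensus.
#'
#' @param consensusLength match-state count of each synthetic model.
#' @param matchProb dominant emission probability of the consensus
#'   residue at each match state.
#' @return A validated \code{\link{IronFamilyDb}}.
#' @export
#' @examples
#' db <- defaultDatabase()
#' length(categories(db))
defaultDatabase <- function(consensusLength = 30, matchProb = 0.95) {
  ext <- function(f) system.file("extdata", f, package = "ironScan",
                                 mustWork = TRUE)
  fam <- .readManifestTable(ext("families.tsv"))
  op <- .readOperonTable(ext("operons.tsv"))
  ru <- .readRuleTable(ext("rules.tsv"))
  models <- list(); refSets <- list()
  cons <- vapply(fam$family_id, .familyConsensus, character(1),
                 len = consensusLength)
  # heme-motif families carry the canonical CxxCH in their consensus
  heme <- !is.na(fam$min_heme_motifs) & fam$min_heme_motifs > 0
  cons[heme] <- paste0(substr(cons[heme], 1, 2), "CAACH",
                       substr(cons[heme], 8, consensusLength))
  stopifnot(!anyDuplicated(cons))
  for (i in seq_len(nrow(fam))) {
    id <- fam$family_id[i]
    h <- makeToyHmm(cons[i], matchProb = matchProb)
    h@name <- id
    if (fam$method[i] == "hmm") {
      bitCutoff(h) <- fam$cutoff[i]
      models[[id]] <- h
    } else {
      refSets[[id]] <- Biostrings::AAStringSet(
        setNames(emitProteins(h, 3, seed = .idSeed(id, salt = 7L)),
                 paste0(id, "_synthetic_ref", 1:3)))
    }
  }
  db <- new("IronFamilyDb", families = fam, operons = op, rules = ru,
            models = models, refSets = refSets, config = .defaultConfig())
  validObject(db)
  db
}

.familyConsensus <- function(id, len = 30) {
  paste(withSeed(.idSeed(id), sample(AMINO, len, replace = TRUE)),
        collapse = "")
}

#' @describeIn IronFamilyDb the family manifest table.
#' @param db an \code{IronFamilyDb}.
#' @export
familyTable <- function(db) db@families

#' @describeIn IronFamilyDb category labels the database can emit (the
#'   full fixed schema).
#' @export
categories <- function(db) categorySchema()

#' @describeIn IronFamilyDb named list of parsed profile HMMs.
#' @export
familyModels <- function(db) db@models

#' @describeIn IronFamilyDb reference protein set of a homology family.
#' @param family a homology-method family id.
#' @export
refSet <- function(db, family) {
  if (!family %in% names(db@refSets))
    stop("no reference set for family '", family, "'", call. = FALSE)
  db@refSets[[family]]
}

#' @describeIn IronFamilyDb the classification rule table.
#' @export
ruleTable <- function(db) db@rules

#' @describeIn IronFamilyDb the configuration defaults attached to the
#'   database.
#' @export
dbConfig <- function(db) db@config

#' Look up an operon definition
#'
#' @param db an \code{\link{IronFamilyDb}}.
#' @param operon_id operon identifier (e.g. \code{"mtrCAB"},
#'   \code{"mam"}).
#' @return List with \code{operon_id}, \code{members} (character vector),
#'   \code{min_fraction}, \code{category_on_success},
#'   \code{category_on_partial} (NA when none).
#' @export
operon <- function(db, operon_id) {
  i <- match(operon_id, db@operons$operon_id)
  if (is.na(i)) stop("unknown operon '", operon_id, "'", call. = FALSE)
  list(operon_id = operon_id,
       members = strsplit(db@operons$member_families[i], ",")[[1]],
       min_fraction = db@operons$min_fraction[i],
       category_on_success = db@operons$category_on_success[i],
       category_on_partial = db@operons$category_on_partial[i])
}

#' Families assigned to a functional category
#'
#' @param db an \code{\link{IronFamilyDb}}.
#' @param label a category label from \code{\link{categorySchema}}.
#' @return The manifest rows of that category, sorted by family id (may
#'   be empty for verdict-only categories such as probable iron
#'   reduction).
#' @export
familiesInCategory <- function(db, label) {
  if (!label %in% categorySchema())
    stop("unknown category '", label, "'; allowed: ",
         paste(categorySchema(), collapse = ", "), call. = FALSE)
  sel <- db@families[db@families$category == label, , drop = FALSE]
  sel <- sel[order(sel$family_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

setMethod("show", "IronFamilyDb", function(object) {
  cat("IronFamilyDb:", nrow(object@families), "families,",
      length(unique(object@families$category)), "populated categories,",
      nrow(object@operons), "operons,", nrow(object@rules), "rules\n")
  cat("  models:", length(object@models), "profile HMMs;",
      length(object@refSets), "homology reference sets\n")
})
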