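## Gene neighborhoods and the classification rule engine. A neighborhood
## is a connected component of annotated genes on one contig, linking
## genes whose ordinal indices differ by at most max_gap. Operon and
## redox rules fire per neighborhood; simple categories yield gene-level
## calls.

#' Group annotated genes into gene neighborhoods
#'
#' Neighborhoods are the connected components of the graph linking
#' annotated genes on the same contig whose gene indices differ by at
#' most \code{maxGap}. Singleton neighborhoods are allowed. The family
#' set of a neighborhood includes secondary hits, so operon rules can see
#' co-located families even when a gene's primary label differs.
#'
#' @param ann annotation data.frame from \code{\link{annotateSample}}.
#' @param maxGap maximum intervening gene-index gap (>= 1).
#' @return List of neighborhoods, each a list with \code{contig_id},
#'   \code{gene_ids}, \code{indices}, \code{span} (min/max index),
#'   \code{families} (union over members), and \code{annotations} (the
#'   member rows).
#' @export
buildNeighborhoods <- function(ann, maxGap = 3) {
  if (maxGap < 1) stop("maxGap must be >= 1", call. = FALSE)
  if (!nrow(ann)) return(list())
  out <- list()
  for (ct in sort(unique(ann$contig_id))) {
    sub <- ann[ann$contig_id == ct, , drop = FALSE]
    idx <- sort(unique(sub$index))
    brk <- c(0, which(diff(idx) > maxGap), length(idx))
    for (b in seq_len(length(brk) - 1)) {
      members <- idx[(brk[b] + 1):brk[b + 1]]
      rows <- sub[sub$index %in% members, , drop = FALSE]
      out[[length(out) + 1]] <- list(
        contig_id = ct,
        gene_ids = unique(rows$gene_id[order(rows$index)]),
        indices = members,
        span = range(members),
        families = sort(unique(rows$family_id)),
        annotations = rows)
    }
  }
  out
}

#' Fraction of an operon's member families present in a neighborhood
#'
#' @param nb one neighborhood from \code{\link{buildNeighborhoods}}.
#' @param od an operon definition from \code{\link{operon}}.
#' @return Completeness in [0, 1]: distinct member families present
#'   divided by total member families.
#' @export
operonCompleteness <- function(nb, od) {
  length(intersect(od$members, nb$families)) / length(od$members)
}

#' Apply the classification ruleset to gene neighborhoods
#'
#' Evaluates the shipped (or user-supplied) rule table per neighborhood:
#' a rule fires when all its required families are present, at least
#' \code{min_any} of its alternative families are present, and none of
#' its forbidden families are (complete-operon rules thereby shadow their
#' partial fallbacks). Rules bound to an operon report the operon
#' completeness of the neighborhood. Two built-in behaviors complement
#' the table: siderophore-synthesis families produce an operon-level call
#' when two or more distinct synthesis families are co-located and
#' low-confidence gene-level calls otherwise, and every primary
#' annotation in a simple category (transport, oxygenases, heme and
#' siderophore transport, regulation, storage) yields a gene-level call.
#'
#' @param nbs neighborhood list from \code{\link{buildNeighborhoods}}.
#' @param db an \code{\link{IronFamilyDb}}.
#' @param sampleId sample identifier recorded on each call.
#' @param rules rule table; defaults to the database's.
#' @return data.frame of category calls: \code{sample_id},
#'   \code{contig_id}, \code{category}, \code{rule_id},
#'   \code{evidence_families}, \code{evidence_genes} (comma-separated,
#'   sorted), \code{completeness} (NA for non-operon rules),
#'   \code{flags}; ordered by (contig, category, rule, evidence).
#' @export
applyRules <- function(nbs, db, sampleId = "sample",
                       rules = ruleTable(db)) {
  fam <- familyTable(db)
  used <- unlist(c(strsplit(.orDash(rules$required_families), ","),
                   strsplit(.orDash(rules$any_of_families), ","),
                   strsplit(.orDash(rules$forbidden_families), ",")))
  unknown <- setdiff(used, fam$family_id)
  if (length(unknown))
    stop("ruleset references unknown families: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- list()
  emit <- function(contig, category, rule_id, famIds, genes,
                   completeness = NA_real_, flags = "") {
    out[[length(out) + 1]] <<- data.frame(
      sample_id = sampleId, contig_id = contig, category = category,
      rule_id = rule_id,
      evidence_families = paste(sort(unique(famIds)), collapse = ","),
      evidence_genes = paste(sort(unique(genes)), collapse = ","),
      completeness = completeness, flags = flags,
      stringsAsFactors = FALSE)
  }
  generic <- c("iron_transport", "heme_oxygenase", "heme_transport",
               "siderophore_transport", "iron_gene_regulation",
               "iron_storage")
  for (nb in nbs) {
    fset <- nb$families
    genesOf <- function(famIds) {
      rows <- nb$annotations[nb$annotations$family_id %in% famIds, ,
                             drop = FALSE]
      rows$gene_id
    }
    for (ri in seq_len(nrow(rules))) {
      req <- .csv(rules$required_families[ri])
      anyOf <- .csv(rules$any_of_families[ri])
      forb <- .csv(rules$forbidden_families[ri])
      if (length(req) && !all(req %in% fset)) next
      if (length(anyOf) && sum(anyOf %in% fset) < rules$min_any[ri]) next
      if (length(forb) && any(forb %in% fset)) next
      involved <- union(req, intersect(anyOf, fset))
      comp <- NA_real_
      if (!is.na(rules$operon_id[ri]))
        comp <- operonCompleteness(nb, operon(db, rules$operon_id[ri]))
      emit(nb$contig_id, rules$category[ri], rules$rule_id[ri],
           involved, genesOf(involved), comp)
    }
    prim <- nb$annotations[nb$annotations$role == "primary", , drop = FALSE]
    synth <- prim[prim$category == "siderophore_synthesis", , drop = FALSE]
    if (length(unique(synth$family_id)) >= 2)
      emit(nb$contig_id, "siderophore_synthesis", "sid_synth_operon",
           synth$family_id, synth$gene_id)
    else if (nrow(synth))
      for (j in seq_len(nrow(synth)))
        emit(nb$contig_id, "siderophore_synthesis", "sid_synth_single",
             synth$family_id[j], synth$gene_id[j], flags = "low_confidence")
    gen <- prim[prim$category %in% generic, , drop = FALSE]
    for (j in seq_len(nrow(gen)))
      emit(nb$contig_id, gen$category[j], "gene_level",
           gen$family_id[j], gen$gene_id[j])
  }
  if (!length(out))
    return(data.frame(sample_id = character(), contig_id = character(),
                      category = character(), rule_id = character(),
                      evidence_families = character(),
                      evidence_genes = character(),
                      completeness = numeric(), flags = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$contig_id, df$category, df$rule_id, df$evidence_genes), ]
  rownames(df) <- NULL
  df
}

#' Run the full per-sample pipeline
#'
#' Annotation, neighborhood construction and rule classification in one
#' call.
#'
#' @param genes a \code{\link{GeneCalls}} object.
#' @param db an \code{\link{IronFamilyDb}}.
#' @param maxGap neighborhood gene-index gap; defaults to the database
#'   configuration.
#' @return List with \code{sample_id}, \code{genes}, \code{annotations},
#'   \code{neighborhoods}, \code{calls}.
#' @export
screenSample <- function(genes, db, maxGap = dbConfig(db)$max_gap) {
  ann <- annotateSample(genes, db)
  nbs <- buildNeighborhoods(ann, maxGap = maxGap)
  calls <- applyRules(nbs, db, sampleId = sampleId(genes))
  list(sample_id = sampleId(genes), genes = genes, annotations = ann,
       neighborhoods = nbs, calls = calls)
}
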