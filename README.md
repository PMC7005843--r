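# ironScan

Annotation of iron acquisition, storage, regulation and redox-cycling
genes in genomes and metagenomes.

Marker genes for dissimilatory iron oxidation and reduction (cyc2,
mtrCAB, mtoAB, omcS/omcZ, ...), siderophore synthesis and transport,
heme uptake and lysis, iron storage, iron gene regulation and
magnetosome formation are poorly served by general annotation pipelines.
ironScan screens predicted proteins against a family database in which
every protein family carries its own detection model and calibrated
acceptance threshold, then classifies hits in their gene-neighborhood
context into twelve functional categories.

## Method at a glance

* **Scoring** — each hmm-method family is a profile HMM (HMMER3 ASCII
  I/O); proteins are scored by uni-local Viterbi in log2 space: uniform
  1/M entry into any match state, free exit, flanks at zero log-odds,

  score = max over local alignments of log2 [ P(path, emissions | model) / P(residues | background) ],

  accepted iff score ≥ the family's calibrated bit cutoff. Families
  without reliable HMMs fall back to Smith–Waterman search (BLOSUM62,
  gap 11/1) against reference sets with e-value E = m·n·2^(−bits) and a
  default cutoff of 1e-10.
* **Filters** — canonical c-type heme motifs (CxxCH, non-overlapping)
  are counted per gene; families may demand a minimum motif count and
  protein length. The shipped instance is the Cyc2 rule: ≥ 1 motif and
  ≥ 375 aa.
* **Rules** — annotated genes are grouped into neighborhoods (gene-index
  gap ≤ 3) and a data-driven rule table emits category calls: complete
  mtrCAB → iron reduction, mtrAB without mtrC → probable iron reduction,
  lone mtoA → possible oxidation/reduction, ≥ 5 of the 10 mam markers →
  magnetosome formation, co-located synthesis families → siderophore
  operon, and so on.
* **Summaries** — category × sample count matrices, normalization to
  100·count/ORFs, row z-scoring, Ward/Euclidean clustering with seeded
  bootstrap support, TSV/Newick export.

The shipped manifest reproduces the published family/category/operon
structure with **synthetic toy models** (deterministic per-family
consensus HMMs); mount a curated model library with `loadManifest()`.
Database-construction utilities (35%/70% homolog filtering, 70%
dereplication, cutoff selection from labelled scores) and a
deterministic fixture generator with truth labels are part of the
package. See the methods vignette
(`vignettes/iron-gene-annotation.Rmd`) for the full model description.

## Worked example

```r
library(ironScan)
db <- defaultDatabase()
db
#> IronFamilyDb: 121 families, 11 populated categories, 10 operons, 23 rules
#>   models: 115 profile HMMs; 6 homology reference sets

# a synthetic sample with planted operons and its truth labels
fx  <- buildFixture(defaultFixtureSpec(1), db)
res <- screenSample(fx$genes, db)
res$calls[, c("contig_id", "category", "rule_id", "evidence_genes", "completeness")]
#>   contig_id category                                            rule_id          evidence_genes                completeness
#> 1 c1        iron_gene_regulation                                gene_level       c1_10                         NA
#> 2 c1        iron_reduction                                      mtrCAB           c1_3,c1_4,c1_5                1.0
#> 3 c2        iron_storage                                        gene_level       c2_12                         NA
#> 4 c2        magnetosome_formation                               mam              c2_2,c2_3,c2_4,c2_5,c2_6,c2_7 0.6
#> 5 c3        iron_oxidation                                      cyc2_cluster1    c3_2                          NA
#> 6 c3        possible_iron_oxidation_and_possible_iron_reduction mtoA             c3_8                          NA
#> 7 c3        siderophore_synthesis                               sid_synth_operon c3_12,c3_13                   NA
```

The planted mtrC–mtrA–mtrB run is called as iron reduction at operon
completeness 1.0; six of the ten mam markers clear the ≥ 50% rule and
yield a magnetosome call at completeness 0.6; the lone mtoA gene lands in
the ambiguity category; two co-located synthesis genes form a siderophore
operon call. Per-gene annotations carry scores against their cutoffs:

```r
head(res$annotations[res$annotations$role == "primary",
                     c("gene_id", "family_id", "score", "cutoff", "margin")], 3)
#>   gene_id family_id     score cutoff   margin
#> 1    c1_3      mtrC  84.67744     30 54.67744
#> 2    c1_4      mtrA  69.08572     30 39.08572
#> 3    c1_5      mtrB 101.20914     30 71.20914
```

A thin command-line front end over the same functions lives at
`inst/scripts/ironscan.R`:

```sh
Rscript inst/scripts/ironscan.R --input sampleA.faa,sampleB.faa --outdir out/
```

writing per-sample gene and call CSVs plus the comparative matrix,
dot-plot table and bootstrap-labelled Newick dendrogram.

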