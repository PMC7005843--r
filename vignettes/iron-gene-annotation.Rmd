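---
title: "Methods: annotating iron acquisition, storage, regulation and redox genes"
author: "ironScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating iron acquisition, storage, regulation and redox genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Dissimilatory iron oxidation and reduction, siderophore-mediated iron
scavenging, heme uptake and lysis, iron storage and the regulators that
balance them are rarely annotated correctly by general-purpose pipelines:
the marker genes (cyc2, mtrCAB, mtoAB, omcS, the mam cluster, NRPS/NIS
siderophore synthetases, TonB-dependent receptors, ...) are either absent
from public HMM collections or drown in homologous non-iron families.
ironScan screens assembled genomes and metagenomes for these repertoires
with a family database that binds each protein family to a detection
model, a calibrated acceptance threshold, optional protein-level filters
and an operon context, and classifies the hits into twelve functional
categories with an operon-aware rule engine.

The twelve categories (fixed order, `categorySchema()`): iron transport,
heme oxygenases, heme transport (including transferrin/lactoferrin
receptors), siderophore synthesis, siderophore transport, iron gene
regulation, iron oxidation, possible iron oxidation / possible iron
reduction (the ambiguity class reserved for MtoAB/PioAB-like conduits and
cluster-3 Cyc2), iron reduction, probable iron reduction, iron storage,
and magnetosome formation. Published family tables sometimes split the
acquisition block into thirteen function rows; here the
transferrin/lactoferrin receptor families are filed under heme transport
so that the schema stays at the canonical twelve labels, and the two
"probable"/"possible" redox labels are verdict categories produced by
rules rather than by any single family.

# Detection model

## Profile-HMM scoring

Each hmm-method family is a profile HMM over the 20-residue alphabet
(match/insert emissions, seven transition probabilities per node, null
background), read from and written to the HMMER3 ASCII format
(`parseHmmer3()`, `writeHmmer3()`). Scoring (`viterbiBits()`) is
**uni-local Viterbi in log2 space**:

* an alignment may enter at any match state with uniform probability
  $1/M$ (the $\log_2 M$ entry cost is folded into the score),
* it exits from any match state for free,
* flanking residues are scored by the null model and therefore contribute
  zero log-odds,
* the score is the maximum over all such alignments of
  $\log_2 \frac{P(\text{path, emissions} \mid \text{model})}{P(\text{emitted residues} \mid \text{background})}.$

Residues outside the 20-letter alphabet (X, B, Z, U, O) score zero
log-odds in every state. No null2/bias composition correction is applied:
every family carries its own calibrated bit cutoff on exactly this scale,
so the scale is consistent between calibration and screening, which is
the property the per-family cutoffs rely on. The kernel is a small C++
dynamic program; the test suite pins it against an exhaustive
path-enumeration oracle on toy models (all alignments of all lengths, M
up to 4, sequences up to 8 residues, >200 cases, tolerance 1e-9 bits).

The choice of a full-sequence local score (rather than a best-domain
score) is deliberate: cutoffs shipped in a manifest are defined against
the package's own score, and an adapter seam (`bestScores()` over any
model list) allows an external search engine to be swapped in with the
same cutoff semantics.

## Homology fallback

Families that lack reliable HMMs (S-layer proteins implicated in iron
reduction, Geobacter-type porin-cytochrome operon members) are searched
by pairwise local alignment against a per-family reference set
(`fallbackSearch()`): BLOSUM62, affine gaps (open 11, extend 1), bit
scores via the gapped Karlin-Altschul constants $\lambda = 0.267$,
$K = 0.041$, and e-values $E = m \, n \, 2^{-\text{bits}}$ over the
search space $m \times$ (total reference residues), with no length or
edge corrections — at the default acceptance threshold of $10^{-10}$ the
corrections are irrelevant. The local alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; the module's contract is the
threshold, and the best reference per gene is kept.

## Protein-level filters

Per-gene heme content is the number of non-overlapping canonical c-type
heme-binding motifs CxxCH, scanned left to right
(`countHemeMotifs()`). Only the canonical spacing is counted; the longer
CxxxCH/CxxxxCH variants are an explicit extension point, not a default.
A family may demand a minimum motif count and a minimum protein length in
the manifest; the Cyc2 rule — at least one motif and at least 375
residues, long enough to encode the fused outer-membrane porin — is the
shipped instance (`cyc2Accept()`), expressed as data
(`min_heme_motifs = 1`, `min_length = 375`) rather than code, so the
filter generalizes to any family.

## Best-hit resolution

All per-gene hits at or above their cutoffs are kept. The primary
annotation is the hit with the greatest margin (bits above cutoff for HMM
hits; $\log_{10}(\text{cutoff}/E)$ for homology hits); ties prefer the
hmm method, then the lexicographically smaller family id. Secondary
passing hits are retained because operon rules need co-located families
even when a gene's primary label differs (e.g. an mtoA-labelled gene
whose mtrA score also passes). Gene-level calls in the simple categories
are generated from primary annotations only, which keeps one gene from
seeding calls in several acquisition categories at once.

# Neighborhoods and rules

Gene order, not nucleotide distance, drives operon context: a
neighborhood is a connected component of annotated genes on one contig
whose ordinal gene indices differ by at most `max_gap` (default 3
intervening genes — tolerant of small insertions while keeping operons
local; the geometry of "gene neighborhood" is otherwise unspecified in
the literature this follows). Plain protein FASTA without coordinates is
accepted, but every gene then sits on a singleton pseudo-contig and
multi-gene rules cannot fire (a warning says so).

The rule engine (`applyRules()`) evaluates a data-driven rule table
(TSV: required families, alternative families with a minimum count,
forbidden families, optional operon binding). Highlights of the shipped
default:

* **iron_oxidation** — cyc2 cluster 1/2, cyc1 or sulfocyanin alone;
  foxABC with at least 2 of 3 co-located; foxEYZ with foxE plus one of
  foxY/foxZ; pioA with pioB.
* **possible oxidation/reduction** — mtoA (with or without mtoB), or
  cluster-3 cyc2.
* **iron_reduction** — complete mtrCAB in one neighborhood; cymA; any of
  omcF/omcS/omcZ; the 8-gene flavin operon at 50% co-location; the two
  Desulfovibrio ferrophilus loci at 3/4 and 3/5; S-layer or
  porin-cytochrome fallback hits with at least two operon members
  co-located.
* **probable_iron_reduction** — mtrAB without mtrC, mtrCB without mtrA,
  or mtoAB with a co-located mtrC.
* **magnetosome_formation** — at least 5 of the 10 mam markers
  (mamA/B/E/K/L/M/O/P/Q/I) in one neighborhood; completeness is reported
  as the fraction of the ten markers present. mamL is counted in the
  denominator even though it is specific to magnetite producers — the
  marker set is treated uniformly.
* **siderophore_synthesis** — two or more distinct synthesis families
  co-located give an operon-level call; a lone synthesis gene is reported
  but flagged `low_confidence`.
* all remaining categories produce one gene-level call per primary
  annotation.

Forbidden families make complete-operon rules shadow their partial
fallbacks structurally: a neighborhood with mtrC, mtrA and mtrB can fire
only `mtrCAB`, never `mtrAB` on the same evidence. The mtoA ambiguity
rule is likewise suppressed when mtrC is co-located, so an
mtoA+mtoB+mtrC neighborhood is classified once, as probable iron
reduction. Operon co-location is required within a single neighborhood,
not mere co-occurrence anywhere in the genome; no strand or intergenic
distance constraints are imposed. Rule evaluation is a pure function of
the neighborhoods and rule table, and the whole classification is
invariant to the input order of genes and families.

# Comparative summaries

`countMatrix()` counts distinct evidence genes per category and sample
(a gene counted once per category); `normalizeMatrix()` rescales to
$100 \times \text{count} / \text{predicted ORFs}$, the denominator being
the sample's total gene calls; `scaleRows()` z-scores category rows with
the sample (n−1) standard deviation, mapping constant rows to zero.
Heatmap scaling is applied to the **normalized** values by default (raw
counts confound genome size with repertoire; the choice is configurable
simply by passing the count matrix instead). Clustering is Ward's
variance-minimizing linkage on Euclidean distances (`hclust`
"ward.D2", the standard "Ward on Euclidean" dialect, recorded in the
export metadata). Cluster uncertainty uses an **ordinary bootstrap over
category rows**: B resampled matrices are re-clustered and each internal
node's support is the percentage of resamples reproducing its leaf set.
This replaces multiscale-bootstrap AU values; plain support percentages
serve the stated purpose — assessing uncertainty in the clustering — and
are seeded, hence byte-stable. With fewer than three samples support is
undefined and omitted. Trees serialize to Newick with support as internal
node labels; matrices and the dot-plot long table to TSV at six
significant digits.

# Database construction utilities

The calibration workflow that produced a curated model library is
exposed as testable primitives:

* `filterHomologs()` — the homolog-gathering rule: at least 35% amino
  acid identity over at least 70% of the query length (both boundaries
  inclusive).
* `dereplicate()` — greedy identity collapse at 70% global identity,
  longest sequences first; identity is matches over alignment columns
  under the same BLOSUM62/11/1 scoring as the fallback search (the
  upstream tool's identity definition is unspecified, so one is fixed
  and documented here).
* `chooseCutoff()` — per-model bit cutoffs from labelled score lists:
  the minimum true-positive score when classes separate; otherwise the
  balanced-accuracy-maximizing threshold over the observed scores, ties
  resolved upward to favor precision. The published calibration was a
  manual inspection with no stated loss; balanced accuracy with a
  precision-favoring tie-break is this package's deterministic stand-in,
  not a claim about the original authors' procedure.

Seed gathering against nr/RefSeq and multiple alignment + `hmmbuild` are
external steps (network-scale databases, external aligner) and are
deliberately out of scope; `loadManifest()` mounts any library built
that way.

# The synthetic model library and fixture generator

The shipped manifest is a faithful skeleton of the published
family/category/operon structure (121 families across the schema, ten
operons, the full rule set), but the models bound to it are **synthetic**:
toy profile HMMs with a 30-residue consensus drawn deterministically from
each family id, dominant match emission 0.95, match-to-match transition
0.9, uniform background, and a uniform 30-bit cutoff (homology families:
three synthetic reference emissions and the 1e-10 e-value default).
Families with a heme-motif requirement carry a CxxCH in their consensus.
Users mount a real calibrated library with `loadManifest()`; everything
downstream of scoring is identical.

`buildFixture()` generates whole samples: planted genes are emissions
from the named families' models (reference copies for homology
families), padded and motif-enforced to satisfy the family's filters;
background genes are i.i.d. draws from the background distribution with
lengths 80–450 aa, a range that brackets the 375-residue Cyc2 boundary
from both sides. At a 0.95 dominant emission a planted 30-node gene
scores ~80–110 bits against its own model while background genes stay
far below the 30-bit cutoffs, so fixture-scale separation is essentially
deterministic and recovery tests do not flake. Each fixture ships its
truth: per-gene family labels and the exact category calls the engine
must produce, computed from the planted layout by an independent
evaluation of the rule table.

What the generator emulates: gene order on contigs, operon co-location,
family-specific length/motif constraints, detection margins. What it
does **not** emulate: real sequence divergence within families,
compositional bias, overlapping or nested operons, fragmented
contig-edge genes, codon-level structure, sequencing error. Passing the
recovery suite therefore demonstrates that the pipeline machinery
(scoring, filters, neighborhoods, rules, summaries) is correct, not that
the synthetic toy models have the sensitivity of the curated library on
real data.

# Numerical and interface choices

* Coordinates are 1-based inclusive on the forward strand (the ORF
  caller's header dialect); ordinal gene index drives all neighborhood
  logic. Stop codons (`*`) are stripped from translations before
  scoring. Genes truncated at contig edges receive no special handling.
* HMMER3 fields are negative natural logs; `*` parses as probability
  zero; a missing COMPO line means a uniform background. Emission and
  transition groups are renormalized after parsing to absorb the text
  encoding's finite precision.
* Ties: hit resolution (margin, then hmm over homology, then family id)
  and rule evaluation order (complete operons before partial fallbacks)
  are total orders, so outputs are byte-identical across runs.
* All randomness (emission, fixtures, bootstrap) flows through a single
  seeded wrapper that restores the caller's RNG state.
* Default problem sizes in the test and acceptance runs: 121-family
  database, 3-contig × 14-gene fixtures at five seeds plus matched
  background-only samples, a 101-point Cyc2 length sweep, and a 10-step
  mam completeness sweep — sizes chosen so the whole suite exercises
  every rule family while remaining a desk-scale computation.

# Known limitations

* The shipped toy models are placeholders for a curated library; real
  screening sensitivity is entirely determined by the mounted models and
  cutoffs.
* The optional cross-validation of hits against a user reference
  database is a no-op adapter seam.
* Forward-algorithm e-values, glocal/multihit alignment modes, and
  composition-corrected bit scores are out of scope for the internal
  scorer.
* GenBank parsing covers the flat-file subset with simple/complement
  (optionally join) CDS locations and `/translation` qualifiers.
* Small regulatory RNAs and heme / Fe-S cluster synthesis pathways are
  outside the family schema by design.
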