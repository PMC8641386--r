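---
title: "Methods: gene-model validation, evidence-driven curation and splicing classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-model validation, evidence-driven curation and splicing classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annocure)
```

This vignette explains the models and procedures behind `annocure`, the
assumptions they make, the parameters that matter, and the choices taken where
the design was genuinely open. The package automates the post-prediction stage
of a plant genome-annotation workflow: a predictor (or a lift-over) has
produced a gene set; transcript, protein and prior-version alignments are
available as evidence; the task is to flag broken models, repair fused and
fragmented predictions, rescue missed genes, label transposable-element ORFs,
assign systematic names, classify alternative-splicing events and reconcile
the result with the previous annotation version.

## Coordinates and containers

All internal coordinates are 0-based half-open; GFF3 I/O is the only place the
1-based inclusive convention appears. This keeps interval arithmetic free of
off-by-one churn — lengths are `end - start`, abutment is `a_end == b_start`.
The `annotation_set` container is a list of four tibbles (genes, transcripts,
exons, CDS segments), which keeps every operation expressible as ordinary
dplyr verbs and every result inspectable as a data frame.

The GFF3 reader is deliberately forgiving, because broken files are this
package's raw material: genes lacking an mRNA child get a synthetic single
transcript built from their exon/CDS children; orphan features are either kept
by synthesizing ancestors (`feature_policy = "lenient"`, the default) or
rejected with the offending ids (`"strict"`); CDS phases are read but
recomputed from segment lengths whenever absent or invalid. UTRs are accepted
as `five_prime_UTR`/`three_prime_UTR` features on input but the exon-minus-CDS
difference is authoritative — files in the wild encode UTRs both ways, and
only the difference is guaranteed consistent.

Translation uses the standard genetic code with stops rendered `*`; a codon
containing any symbol outside A/C/G/T translates to `X` (deterministic
handling of ambiguity), and a trailing partial codon is dropped with a
warning rather than an error, since partial codons are precisely one of the
defects the validator must see.

## Validation

`check_gene()` decomposes "interrupted ORF" into observable symptoms:

| flag | condition |
|---|---|
| `MISSING_FEATURE` | a transcript lacks exons or CDS segments |
| `OUT_OF_BOUNDS` | a segment extends beyond its sequence |
| `CDS_OUTSIDE_EXON` | a CDS segment not contained in one exon |
| `CDS_NOT_MULTIPLE_OF_THREE` | total CDS length mod 3 ≠ 0 |
| `PREMATURE_STOP` | `*` before the final codon of the translation |
| `MISSING_START` | first codon ≠ ATG |
| `MISSING_STOP` | final codon ∉ {TAA, TAG, TGA} |

A multi-transcript gene is flagged if any transcript is flagged. Frameshifts
are detected only through their observable symptoms (frame errors, premature
stops); no alignment-based frameshift calling is attempted. `MISSING_START`
and `MISSING_STOP` are "incomplete gene" flags; by default they exclude a gene
from the clean set (`export_clean(..., treat_incomplete_as_error = TRUE)`),
matching a strict evidence filter — an incomplete model is a poor protein
evidence donor — but the switch exists because some downstream uses only care
about internal consistency.

## Evidence-driven curation

Manual split/merge curation is guided by qualitative judgments ("several
proteins support two genes here"). `curation_config()` fixes those judgments
as explicit, tunable rules so the procedure is reproducible:

* `min_cluster_gap` (default 1 bp): evidence alignments whose extents overlap
  or abut join one cluster; a sweep over sorted extents builds connected
  components per strand.
* **Split rule**: a gene is split iff the evidence overlapping it forms ≥ 2
  clusters, *every* cluster contains at least one protein or prior-gene
  alignment (expression-only clusters do not anchor a split: assembled
  transcripts fragment too easily), and no single alignment bridges two
  clusters — bridging evidence merges the clusters by construction, which
  implements the veto structurally. Boundaries fall at the midpoints of
  inter-cluster gaps: symmetric and deterministic. When a prior-version gene
  overlaps a cluster, the replacement copies its exon/CDS structure; otherwise
  the original model is trimmed at the boundary, and if that cut would leave a
  coding length not divisible by three the whole action is skipped and logged
  `UNRESOLVED` rather than emitting a frameshifted model.
* **Merge rule** (`min_reciprocal_overlap_fraction` 0.5,
  `required_merge_support` 2): a maximal run of same-strand,
  coordinate-adjacent genes merges iff at least two evidences each cover every
  gene of the run by ≥ 50% of its exonic length, at least one of them a
  protein or long read. Adjacency means consecutive in coordinate order with
  the same strand; an intervening opposite-strand gene breaks a run. Coverage
  is measured against exonic length, not span, so a long intron cannot dilute
  genuine support. The merged gene's transcript is the union of exons and its
  CDS is recomputed as the longest ATG-initiated, stop-terminated ORF of the
  spliced union (leftmost on ties) — there is no principled way to stitch two
  partial CDSs, and the longest ORF is the standard neutral choice.
* **Rescue rule** (`rescue_min_protein_coverage` 0.5, ≥ semantics): a prior
  gene is added iff it validates clean, overlaps no new gene on the same
  strand, and protein evidence covers at least half of its span. Rescued genes
  keep their structure under new ids.

Candidates are processed left to right per sequence and a gene consumed by one
action is skipped by later ones — determinism over cleverness. After every run
the bookkeeping identity
`out = in − split_in + split_out − merge_in + merge_out + rescues`
is asserted; a violation is a bug, not a warning.

## TE labeling, naming, version mapping

A gene is a putative transposable element iff the union of repeat intervals
covers ≥ 50% of its genomic span (strand-agnostic — repeats hit either strand)
or its Pfam assignments intersect the TE domain table (reverse transcriptase,
integrase, retrotransposon, LTR families). Span rather than exon union is the
denominator: this matches a plain interval-intersection workflow on gene
features, and TE-derived genes are typically covered wall to wall. The two
criteria are OR-combined for the label but reported separately in the summary.
Labeling only sets an attribute; structures are never mutated, so the
threshold can be re-examined cheaply (the labeled set is monotone
non-increasing in the threshold, and a test asserts it).

Locus names follow `<prefix><version><LG n|sc n>G<number>` with numbers
starting at 10 and stepping by 10 along each sequence — the gaps leave room
for future insertions between tens. "First gene at the 5′ end" is interpreted
as the sequence's left end regardless of gene strand, the only total order
well-defined for mixed-strand gene sets; ties break by end coordinate then old
id.

Version mapping draws an edge between an old and a new gene iff they share
sequence and strand and overlap by ≥ 50% of the shorter gene's span
(span, not exonic length — the genome-arithmetic analogue of a feature-level
intersection). Connected components of the bipartite graph become entries
classified by shape (one-to-one, one-to-many, many-to-one, many-to-many,
old-only, new-only); every gene lands in exactly one entry, and swapping the
two sets transposes the relations. Homology-based mapping (protein identity
and coverage) is out of scope; coordinates are the sole criterion.
`percent()` reproduces report-style ratios: 100·n/d rounded half-away-from-zero
to the requested digits.

## Alternative-splicing classification

Isoforms are grouped into loci by transitive same-strand exonic overlap —
sense/antisense pairs deliberately fall into separate loci. For each
transcript pair of a locus, introns are compared inside the pair's overlap
region; introns present in exactly one transcript are clustered by
overlap-or-abutment, and each cluster is one elementary event, classified
solely from the two intron substructures between the shared flanks:

* one side 1 intron, other side none → **IR**;
* 1 vs 1 sharing the donor → **AA**, sharing the acceptor → **AD**
  (donor/acceptor assignment is strand-aware, so the same coordinate pattern
  swaps type between strands);
* 1 vs 2 with matching outer boundaries → **ES** (the 2-intron side carries
  the extra exon);
* 2 vs 2 with matching outer boundaries and disjoint middle exons → **MX**;
* anything else → **COMPLEX**.

Events are defined pairwise and deduplicated across pairs by flanks and
variant structures, with transcript ids accumulated per side. This is simpler
and oracle-checkable, at the declared cost that counts may differ from a full
splicing-graph grouping when more than two isoforms interlock; the test suite
checks equivalence against an independent base-resolution enumerator on random
loci.

An event is **canonical** iff every participating intron has a canonical donor
and acceptor 2-mer (default GT–AG only; GC–AG or AT–AC can be added through
`splice_site_rules()` — GT–AG is the minimal uncontroversial set, and the set
is a parameter precisely because conventions differ) and meets the minimum
intron length (default 20 bp, the "basic splicing rules" stand-in together
with donor-before-acceptor ordering). An event is **in the UTR** iff its
variable region overlaps the CDS of *no* transcript in the locus — any overlap
disqualifies; a CDS-less locus localizes to UTR with a warning rather than an
error, since isoform-only inputs legitimately lack CDS.

## The synthetic-data generator

`simulate_bundle()` emulates the study conditions the workflow is meant for: a
few hundred protein-coding genes on linkage-group- and scaffold-named
sequences (GC 0.36, a Brassicaceae-like composition — cosmetic), 2–5 exons per
gene with 80–220 bp GT–AG introns and 60–240 bp coding exons, short UTR
margins with an ATG-free 5′ UTR, a quarter of multi-exon genes carrying an
intron in the 3′ UTR. Genes are written *into* the genome, so the clean set
validates clean by construction for any seed (a tested invariant). On top of
the truth it plants, with full ground-truth records: fusions (two adjacent
same-strand genes presented as one model), fissions (one gene presented as two
fragments), premature stops (a mid-CDS codon mutated to TGA), frame errors (a
1-bp CDS shrink), missing features (CDS rows deleted), repeats covering
selected genes at 60% (and sub-threshold 35% negative controls), TE and
non-TE Pfam assignments, and one extra isoform per selected gene realizing a
requested ES/AA/AD/MX/IR event, canonical or not, in CDS or UTR. The default
study bundle uses 200 genes, 20 fusions, 20 fissions and 12 sequence/format
corruptions on four ~170 kb sequences — large enough that detection rules face
tens of independent cases, small enough that the whole suite runs in minutes
on one CPU.

Design details worth knowing:

* One master seed fans out to fixed per-operation substreams, so adding one
  generator call never perturbs the others, and sequence *i* depends only on
  (seed, *i*).
* Alternative splice sites for planted isoforms are written only inside
  existing introns, so the primary models stay clean; isoform CDSs are
  assigned explicitly (the premature-termination ORF for retained CDS introns,
  the unchanged ORF for UTR events) rather than re-derived, so the planted
  UTR/CDS localization is guaranteed by construction. Isoform planting uses
  plus-strand genes; the classifier's strand handling is exercised by
  dedicated hand-built minus-strand tests instead.
* Fusion and fission artifacts are *structurally* broken models (a fused model
  contains the first gene's stop codon); they are curation's targets, so the
  validator's precision/recall is evaluated on the sequence/format corruptions
  with those artifacts identified via the truth table and excluded from the
  denominator.
* Evidence is emitted at alignment-block resolution (protein blocks = CDS
  segments, long reads = exon chains, prior genes = gene copies); there is no
  read-level simulation, no error model, no coverage depth. Passing tests
  therefore demonstrate the interval logic and decision rules, not robustness
  to alignment noise, soft-clipping or mapping ambiguity in real data.

## Numerical and degenerate-input choices

Percent formatting rounds half away from zero (report convention), not
banker's rounding. Split boundaries use integer floor of the gap midpoint.
Merge ORF ties break leftmost. Empty inputs are legal everywhere: an empty
annotation writes a pragma-only GFF3, empty evidence yields zero curation
actions while later stages still run, an empty candidate list is the identity
transform with an empty log. Curation is idempotent: a second pass over its
own output performs zero actions (tested). Pipelines are deterministic: the
same inputs produce byte-identical report bundles (tested).

## Known limitations

* Coverage-fraction rules use genomic span or exonic length as stated; no
  alignment scores, identities or AED-style measures are consulted.
* The merge rule assumes fragments are adjacent with no intervening gene;
  interleaved fragmentation is not repaired.
* Pairwise event deduplication can differ from splicing-graph event counting
  on loci where three or more isoforms interlock in one variable region.
* The rescue step trusts the prior version's structure verbatim; it does not
  re-fit boundaries against the evidence.
* The generator does not emulate tandem gene arrays, nested genes,
  trans-splicing, or repeat-driven mis-assembly — the error modes it plants
  are the ones the rules are designed to repair, so end-to-end recovery rates
  on synthetic data are upper bounds for real annotations.
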