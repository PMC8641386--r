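# annocure

Evidence-driven quality control and curation of plant gene annotations.

## The problem

De novo genome annotation pipelines (MAKER and friends) and lift-over
migrations of older gene sets both leave systematic damage behind:
interrupted open reading frames (premature stop codons, missing start or stop,
coding lengths not divisible by three), formatting errors that break standard
GFF parsers, gene models that fuse tandem duplicates into one prediction or
fragment one gene into several, transposable-element ORFs masquerading as
genes, and isoform sets whose alternative-splicing structure nobody has
classified. Fixing these by hand in a genome browser does not scale; `annocure`
packages the whole post-prediction workflow as composable, testable functions
for people producing or consuming plant genome annotations:

* **validate** — flag every gene model with `MISSING_FEATURE`,
  `CDS_NOT_MULTIPLE_OF_THREE`, `PREMATURE_STOP`, `MISSING_START`,
  `MISSING_STOP`, `OUT_OF_BOUNDS` or `CDS_OUTSIDE_EXON`, and export the
  error-free subset usable as evidence.
* **curate** — detect incorrectly merged predictions (two disjoint clusters of
  protein/prior-gene evidence under one model, no bridging read) and split
  them; detect incorrectly split predictions (several alignments each covering
  every gene of an adjacent same-strand run by ≥ 50% of its exonic length) and
  merge them, rebuilding the coding sequence as the longest ATG-initiated ORF;
  rescue clean prior-version genes that the predictor missed but protein
  evidence covers by ≥ 50%. Every action is logged and the bookkeeping
  identity `out = in − split_in + split_out − merge_in + merge_out + rescues`
  is asserted on every run.
* **TE-label** — mark putative transposable-element genes: repeat coverage of
  the gene span ≥ 50%, or a Pfam domain from the reverse
  transcriptase/integrase/retrotransposon/LTR set (PF00078, PF07727, PF13456,
  PF13966, PF00665, PF13976, PF03732, PF08284, PF14223, PF14244).
* **rename** — systematic locus identifiers such as `Aa31LG1G10`
  (species prefix, annotation version, linkage group or scaffold, gene number
  starting at 10 and stepping by 10 along each sequence).
* **AS-classify** — Astalavista-style classification of elementary
  alternative-splicing events between a locus's isoforms: exon skipping (ES),
  alternative acceptor (AA), alternative donor (AD), mutually exclusive exons
  (MX), intron retention (IR), anything else COMPLEX; canonical-splice-site
  flags (GT–AG by default, strand-aware, minimum intron length) and UTR vs CDS
  localization of each event's variable region.
* **version-map** — cross-version gene correspondence (one-to-one, split,
  merged, lost, novel) by same-strand overlap of at least 50% of the shorter
  gene's span, with the ratio bookkeeping (`percent()`) used in annotation
  reports.
* **simulate** — a deterministic generator of genomes, clean and corrupted
  annotations, evidence tracks, repeats and isoform sets with known ground
  truth, so the entire workflow is testable without any external data.

Everything is tidyverse-shaped: the core `annotation_set` container holds
tibbles, every result (validation report, curation log, event table, version
map) is a tibble with `tidy()`/`glance()` methods and `autoplot()` figures,
and functions compose with the pipe.

## Worked example

Simulate a study bundle (60 true genes on two sequences; 3 planted fusions,
3 fissions, 6 sequence/format corruptions, 4 TE genes, 8 planted splicing
events), then run the full workflow:

```r
library(annocure)

bundle <- simulate_bundle(seed = 42, n_genes = 60, n_sequences = 2,
                          seq_length = 130000, n_fusions = 3, n_fissions = 3,
                          corruption_recipe = list(premature_stop = 2,
                                                   cds_mod3 = 2,
                                                   missing_feature = 2),
                          n_te_genes = 4)

glance(validate_set(bundle$predicted_set, bundle$genome))
#>   n_genes n_flagged MISSING_FEATURE CDS_NOT_MULTIPLE_OF_THREE PREMATURE_STOP ...
#> 1      60        15               2                         2              5
```

15 flagged models: the 6 planted sequence/format corruptions plus the fusion
and fission artifacts, which are structurally broken by construction (a fused
model carries an internal stop where the first gene ended).

```r
result <- run_pipeline(bundle$predicted_set, bundle$genome, bundle$evidence,
                       prior_set = bundle$prior_set, repeats = bundle$repeats,
                       domains = bundle$domains, isoforms = bundle$isoform_set)
glance(result$log)
#>   n_split n_split_outputs n_merge n_merge_inputs n_rescue n_unresolved
#> 1       3               6       3              6        0            0

result$report$versions_table
#>   metric           count
#> 1 raw_genes           60
#> 2 interrupted_orfs     6
#> 3 putative_tes         9
#> 4 total_correct       45

result$report$as_table
#>   label    total_events canonical_events pct_canonical classified_events ...
#> 1 isoforms            8                7          87.5                 8

head(locus_name_map(result$set), 3)
#>   old_id new_name
#> 1 g0001  Aa31LG1G10
#> 2 g0003  Aa31LG1G20
#> 3 g0005  Aa31LG1G30
```

The three planted fusions were split back into six genes, the three fissions
merged back, the six interrupted ORFs are exactly the planted corruptions
(fusion/fission artifacts have been repaired away), nine genes are labeled
putative TEs (repeat coverage or TE domain), 7 of 8 planted splicing events
are canonical (one was planted with a CT–AC acceptor), and locus names follow
the `Aa31LG1G10` convention. `autoplot()` on `result$validation`,
`result$log`, `result$events` or `result$version_map` draws the corresponding
summary figure.

A thin command-line wrapper over the same functions ships in
`inst/cli/annocure.R` (subcommands `validate`, `curate`, `te-label`, `rename`,
`as-classify`, `version-map`, `simulate`, `run`).

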