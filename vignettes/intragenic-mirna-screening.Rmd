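---
title: "Screening genome annotation for intragenic microRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genome annotation for intragenic microRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirhost)
```

## The screening model

Roughly half of annotated vertebrate miRNA genes do not sit in
intergenic space: their precursor hairpins lie inside the boundaries of
another gene, usually in an intron of a protein-coding host, sometimes
in an exon, a UTR, or a non-coding host such as a lincRNA or snoRNA
gene. Because a sense-oriented resident miRNA can share its host's
promoter and primary transcript, intragenic miRNA/host pairs are prime
candidates for co-expression and co-regulation, and knowing exactly
*where* a miRNA sits in its host matters for interpreting host-gene
knockouts, epigenetic silencing, and variant associations.

`mirhost` implements that screen as a small set of composable
operations over standard annotation formats:

1. **Host assignment** (`assign_hosts`, `build_catalog`). A miRNA
   precursor is *intragenic* when its interval is fully contained in a
   gene span on the same chromosome and strand. Containment is closed
   at both ends: a precursor coterminous with the gene boundary counts.
   A precursor inside two overlapping genes yields two assignments (the
   HOXB3/HOXB4-type case). Opposite-strand containments ("antisense")
   and same-strand partial overlaps are tallied separately and excluded
   from the catalog, because sense containment is what licenses the
   shared-promoter interpretation; opposite-strand *partial* overlaps
   fall in neither tally. The containment query runs on
   `GenomicRanges::findOverlaps`; an all-pairs brute-force scan exists
   only in the test suite as an independent oracle.

2. **Transcript-resolved classification** (`classify_in_transcript`).
   Against each transcript of the host, the precursor is `five_utr` or
   `three_utr` when fully inside the spliced UTR (UTR takes precedence
   over the exon ordinal, matching how curated tables print "5'-UTR"
   rather than "exon 1"), `intron k` / `exon k` when fully inside the
   k-th intron or exon counted in transcription direction (so intron 1
   is the first intron on either strand), and `junction` when it
   straddles an exon–intron boundary. A precursor inside the gene span
   but inside no transcript span is `gene-body` — a real situation with
   multi-transcript genes whose transcript spans do not tile the locus,
   and one that must not be silently dropped.

3. **Aggregation** (`aggregate_assignment`). Placements across all
   transcripts of one host are folded into a canonical label — kind
   groups in the fixed order 5'-UTR, exon, intron, 3'-UTR, junction,
   each with ascending deduplicated ordinals, e.g.
   `exon 7; intron 4, 5, 6, 14, 15` — and a category: the single kind
   if only one occurs, `mixed` if several kinds occur. Any junction
   placement forces `mixed`, since a junction-straddling miRNA is
   exonic or intronic depending on splice choice; these rows are thereby
   flagged for review rather than given a misleading single label.

4. **Clusters and biotypes** (`detect_clusters`,
   `partition_biotypes`). A cluster is a host with two or more resident
   miRNAs — the polycistronic-transcript reading. Proximity-based
   clustering (miRNAs within some distance of each other regardless of
   host) is a different notion and out of scope. Each distinct
   intragenic miRNA is partitioned once into protein-coding-only hosts,
   ncRNA-only hosts, or both.

5. **Cross-species conservation** (`find_conserved_pairs`). Two
   intragenic miRNAs in different species are the "same" miRNA for
   screening purposes when their names unify — and their hosts must be
   linked in a user-supplied orthology table. Name unification is
   tiered: tier 1 strips the species prefix and the trailing paralog
   counter (`hsa-mir-103a-1` → `mir-103a`); tier 2 additionally strips
   a single trailing letter variant (`mir-103a` → `mir-103`), except
   for the `let-7` family, whose letters name distinct members and must
   never be collapsed; an explicit override table handles cases no
   normalization can match (chicken `mir-204-2` standing in for
   mammalian `mir-211`). The lowest sufficient tier is recorded per
   pair so that users can audit tier-2 matches, which can in principle
   merge true paralogs. A conserved pair is keyed by (stem, orthologous
   host group): two members of one cluster in the same host are two
   pairs.

6. **Seed variants** (`project_seed`, `find_seed_variants`). The seed —
   positions 2–8 (default) or 2–7 from the mature 5' end — is projected
   to genomic coordinates strand-awarely and overlapped with variant
   positions. An indel counts when any base of its reference footprint
   touches the seed; multi-allelic records count once, because the
   quantity of interest is *polymorphic miRNA genes*, not alleles. A
   precursor is polymorphic when any of its matures has a hit.

## Conventions and numerical choices

* **Coordinates** are 1-based and inclusive everywhere — the native
  convention of GFF/GTF files and of IRanges. Keeping one convention
  end to end removes the entire class of off-by-one conversion bugs; no
  boundary translation exists in the package.
* **Chromosome names** are harmonized by stripping a leading `chr`
  (case-insensitive) plus an optional user alias table, then compared
  exactly; miRNA and gene annotations routinely disagree on this.
* **Percentages** (intragenic fraction, seed-polymorphism rate) are
  *truncated* to one decimal, not rounded: 849/1600 = 53.0625% is
  reported as 53.0. This matches how such fractions are conventionally
  printed in the screening literature this package follows (53.0%,
  48.8%, 42.0%, 14.2% — all floor values of the underlying ratios).
* **Unknown biotypes** map to `other_ncRNA` with a logged note rather
  than an error; annotation vocabularies grow faster than enumerations.
* **Ties and order**: catalog rows sort by (chrom, start, precursor,
  gene); cluster members by genomic start; all outputs are
  deterministic functions of their inputs.

## What the synthetic generator emulates

Real annotation is unavailable offline and too large for unit tests, so
`generate_species()` builds a miniature genome whose every feature is
planted *by construction*: for each placement class the generator
first builds a host gene whose structure guarantees the class (an
intron big enough to hold a hairpin; a two-transcript gene where the
same interval is intron of one transcript and exon of the other for the
`mixed` class; two transcripts with disjoint spans for `gene_body`; two
overlapping same-strand genes for `dual_host`), then samples the miRNA
interval inside the guaranteeing feature. Before returning, an internal
per-base labeller re-derives every planted label; a mismatch aborts
generation. The manifest is therefore ground truth, not a probabilistic
expectation, and recovery tests demand exact equality.

Default scale — the configuration the recovery checks run at — is 200
planted intragenic miRNAs across all eight classes, 100 decoys
(antisense, intergenic, partial overlap), about 280 genes on 3
chromosomes, 24 variants (12 in seeds, 12 just outside), and, in trio
mode, 27 conserved cross-species groups (15% matching only through the
override table, 25% through tier-2 letter stripping) against 40
distractors that share stems without orthologous hosts or vice versa.
These sizes keep a 20-seed recovery sweep around a minute on one CPU
while exercising every code path.

What the generator does **not** emulate, and what passing tests
therefore do not establish about real data: nucleotide sequence (no
FASTA; hairpin plausibility is never checked), realistic chromosome
lengths or gene density, nested/overlapping transcript pathologies
beyond the planted ones, population-genetic structure of variants, and
annotation errors (the readers validate rather than repair). Real
screens also inherit whatever curation errors the source databases
carry; on real inputs the counts are estimates that move with every
annotation release.

## Reproducibility

All generator randomness flows through a single seed
(`generate_species(cfg, seed = ...)`); identical (config, seed) pairs
produce byte-identical files, which the test suite asserts. The
generator saves and restores the caller's RNG state, so it composes
with user code. `scripts/acceptance.R --seed N --out f.json` re-runs
the fixture tallies, a 20-seed recovery sweep, a 1000-instance oracle
comparison, the trio conservation screen with override ablation, the
seed-variant screen, and the determinism check, writing each quantity
with the problem size it was computed at.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config()
sp <- generate_species(cfg, seed = 42, outdir = "sim")
mirnas <- read_mirna_annotation(sp$paths$mirna_gff3)
genes  <- read_gene_annotation(sp$paths$gene_gtf, dialect = "gtf")
catalog <- build_catalog(mirnas, genes, species = "synthA")
catalog
cat(render_summary(catalog$summary, format = "text"), sep = "\n")
hits <- find_seed_variants(mirnas, read_variant_table(sp$paths$vcf))
seed_polymorphism_summary(catalog, hits)
```

## Known limitations

* Orthology is consumed, never inferred; without a link table the
  conservation screen finds nothing.
* Tier-2 name matching can merge distinct paralogs when a species
  carries both a lettered and an unlettered form; `match_tier` is
  reported precisely so such pairs can be audited or filtered.
* The `junction → mixed` rule is conservative: a miRNA overlapping an
  exon–intron boundary in *every* transcript still reports `mixed`.
* Partial sense overlaps are counted, not characterized; if partial
  containments matter for an analysis they need a different screen.
* Gene symbols are carried verbatim from the annotation with no
  nomenclature re-unification; cross-dataset joins should use stable
  gene identifiers.
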