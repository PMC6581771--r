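---
title: "Methods: family-based rare-variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## The analysis model

`famseg` implements a prioritization strategy for rare, possibly
family-specific variants in small pedigrees ascertained for a common
complex disease. The underlying genetic model is dominant-like transmission
of a rare heterozygous allele from an affected parent to an affected child,
combined with the assumption that causal genes leave a transcriptional
footprint in disease-relevant tissue and act through a shared pathway. None
of these assumptions is tested by the pipeline itself; they define which
variants survive it. The cascade is a conjunction of independent filters:

1. **Technical quality.** A variant site is dropped when three or more
   variant positions fall within any 10 bp window (a signature of local
   misalignment), when site mapping quality is below 30, or when any
   non-missing genotype of the family under analysis has depth below 5 or
   genotype quality below 30. All thresholds are strict `<` exclusions, so
   boundary values survive. Missing quality fields count as failures —
   a deliberately conservative reading, since a variant without quality
   evidence cannot be shown to be reliable.
2. **Functional class.** Only NS/SS/I variants proceed: nonsynonymous
   substitutions (including stop gain/loss), canonical splice-site
   disruptions, and coding indels. Splice sites are defined purely by the
   canonical dinucleotide positions (intron offsets ±1 and ±2); external
   splice-strength predictors are consumed, if at all, as annotations and
   are never recomputed.
3. **Novelty.** Variants present in a user-supplied known-variant list (a
   stand-in for dbSNP/1000 Genomes-style databases) are removed by exact
   (chrom, pos, ref, alt) key.
4. **Co-segregation.** A variant is retained when at least one affected
   parent–child pair is heterozygous in both members. Unaffected carriers
   elsewhere in the family do not disqualify a variant at this stage —
   penetrance is not assumed complete in relatives outside the
   ascertainment pair. Homozygous-alt carriers do not qualify under the
   strict heterozygous model; `allow_hom = TRUE` relaxes this for
   sensitivity analysis. In families with several affected pairs, any
   qualifying pair suffices, which allows distinct maternal and paternal
   variants to co-segregate in the same family.
5. **Cross-family recurrence** (reported, not required downstream): genes
   whose qualifying variants occur in two or more families. This mirrors
   the first-pass analysis of such designs; genes recurring for technical
   reasons tend to surface here, which is why the final report does not
   condition on it.
6. **Conjoint evidence.** A candidate variant reaches the final report when
   its gene (a) is differentially expressed between case and control
   profiles, (b) belongs to at least one significantly enriched gene set,
   and (c) passes the damage assessment. Each conjunct can be ablated
   independently in `build_report()`.

## Tunable parameters

All thresholds live in `filter_params()`:

| parameter | default | units | rationale |
|---|---|---|---|
| `cluster_window_bp` / `cluster_min_count` | 10 / 3 | bp / positions | published cluster exclusion ("3 or more within 10 bp") |
| `min_depth` | 5 | reads | published depth exclusion |
| `min_site_mq`, `min_gq` | 30 | Phred | published mapping/genotype-quality exclusions |
| `deg_fdr` | 0.05 | — | conventional FDR level |
| `deg_min_abs_log2fc` | 1.0 | log2 units | two-fold change, the conventional microarray filter |
| `enrich_alpha` | 0.05 | — | conventional significance level for pathways |
| `ease_mode` | TRUE | — | DAVID-style conservative enrichment |
| `damaging_min_votes` | 2 | predictors | consensus of at least two of SIFT/PolyPhen2/PhyloP/MutationTaster |
| `allow_hom` | FALSE | — | strict heterozygous transmission model |

"Within 10 bp" is interpreted as *any* fixed-length window of 10
consecutive positions: a variant in any qualifying window is removed, not
only maximal clusters. This reading is order-independent and is what the
exhaustive window-enumeration oracle in the test suite checks. The cluster
filter operates at site level across the whole cohort; depth and genotype
quality are evaluated per genotype (FORMAT fields) over the members of the
family being analysed, and mapping quality per site (INFO), matching common
caller output. A site can therefore fail quality in one family and pass in
another.

## Differential expression

The DEG stage is a per-gene Welch two-sample *t* test on log2-scale
intensities with Benjamini–Hochberg adjustment across genes and a
fold-change filter (`is_deg = q <= deg_fdr & |log2FC| >= deg_min_abs_log2fc`).
This deliberately simple analysis was chosen over moderated-variance
methods (limma-style) because it is fully specified by textbook formulas,
has no tuning beyond the two thresholds, and can be targeted exactly by the
synthetic generator; it is also well within the operating regime of
microarray group comparisons with a handful of samples per arm. Genes with
zero variance in both groups receive p = 1 when the group means are equal
(no evidence) and p = 0 when they differ (infinite *t* in the limit).
Moderated-variance modelling, probe-level normalization and batch
correction are out of scope; the matrix is assumed gene-level and
normalized.

## Enrichment

Over-representation of a query of *n* genes in a set of size *K* within a
universe of *N* genes is the hypergeometric upper tail P(X ≥ k). With
`ease_mode = TRUE` the EASE score is computed instead — the tail with one
hit removed, P(X ≥ k − 1), and p = 1 whenever k ≤ 1 — a deliberately
conservative penalization of single-gene overlaps. P-values are
BH-adjusted across sets. The background universe defaults to all genes in
the gene-model file, which keeps the test self-contained and reproducible;
an explicit universe can be supplied. Because enrichment p-values are
sharply sensitive to N, K and the background definition, pathway p-values
from other tools (with their own database snapshots and backgrounds) are
not comparable and are not targets of this package.

## Damage assessment

`predictor_consensus()` counts deleterious-class calls (damaging /
conserved / disease-causing) across the four consumed predictors; missing
predictors are non-votes. In the final conjunction this consensus applies
to substitution-type consequences. Loss-of-function categories — canonical
splice-donor/acceptor disruptions, frameshifts, stop gains — qualify by
category: missense predictors do not score splice variants (they carry no
amino-acid change), and the canonical-dinucleotide call *is* the package's
computed damage assessment for them. Without this rule a splice variant
carrying only a single predictor annotation could never be reported, which
would contradict the transmission evidence that put it in the candidate
list.

## The synthetic-data generator

`generate_scenario()` emits a complete, internally consistent input bundle
with ground truth, so that end-to-end recovery is checkable exactly. The
packaged default configuration (`scenario_config()`) encodes the study
conditions the package is modelled on:

- **Four pedigrees**: three trios with an affected mother–child pair and
  one 12-member, three-generation family with seven affected members in
  two sibships, including an affected married-in parent. The extended
  family carries two distinct causal variants on the maternal and paternal
  sides, and one child carries both (the compound-heterozygote flag's
  positive control).
- **Three planted causal variants**: a missense at CDS position 603 in a
  GAA codon (residue 201, `p.E201D`), a missense at CDS position 322 in an
  AGC codon (residue 108, `p.S108R`), and a `c.502+1G>A` splice-donor
  disruption in a two-exon gene whose first exon carries 502 coding bases.
  Carriers are heterozygous exactly as configured; an affected founder
  carries the splice variant so that two carrier sibships remain
  Mendelian-consistent.
- **Decoy shared genes**: five heterozygous missense variants in three
  genes, co-segregating in exactly two families each — recovered by the
  cross-family stage but absent from the DEG list, so they vanish in the
  conjoint step.
- **Negative decoys**: variants shared only with an unaffected parent,
  with a homozygous parent, present in the known database, failing each
  quality criterion, and a deliberate three-variant cluster — one per
  removal mechanism, all bookkept with their expected removal stage.
- **Expression cohort**: 20,000 genes, 7 cases vs 5 controls, 1117 planted
  DE genes with a mean case shift of 100 × the within-group SD (0.1 log2
  units, random sign) and all null genes centred at zero. Under these
  conditions DEG recovery is exact: planted genes have |log2 FC| ≈ 10 ≫ 1
  and vanishing p, while null genes cannot reach the two-fold filter
  (their log2 FC standard error is ≈ 0.06).
- **Gene sets**: one focal-adhesion-like set containing the three causal
  genes plus two non-candidate genes, and four decoy sets of background
  genes.
- **1000 gene models** across five toy chromosomes (4 kb slots, CDS of
  100–210 codons, mixed strands; no UTRs — coding regions span the exon
  extremes). The universe size is a design choice: with ~25 candidate
  genes and a 22-gene DEG intersection, a universe must be large enough
  for a 3-of-5 pathway overlap to be statistically surprising (at
  N = 1000 the EASE tail is ≈ 0.004, surviving BH across five sets); in a
  universe of a few dozen genes the same overlap is unremarkable and the
  conjoint logic could not be exercised.

Design choices that keep the ground truth exact rather than probabilistic:
background variants falling in coding sequence are always placed in the
known-variant set, and only intergenic background variants can be novel
(at 1 − `known_db_coverage`). Chance novel coding variants would otherwise
co-segregate in two or more families in an appreciable fraction of runs,
making the cross-family and intersection counts seed-dependent. All
variant sites except the deliberate cluster are kept at least 20 bp apart
for the same reason. Consequently the generator does **not** emulate:
novel functional background variation (every novel NS/SS/I variant is
planted), realistic allele-frequency spectra or linkage disequilibrium,
sequencing reads, probe-level noise, or transcript isoforms. A green
end-to-end suite therefore demonstrates that the cascade logic is correct
and deterministic, not that the method is robust to the noise structure of
real genomes.

Randomness is handled by deriving one 31-bit seed per emitted file from
the master seed and a stream name, so adding a file type never perturbs
the others; identical seeds give byte-identical bundles.

## Numerical and representational choices

- Coordinates are 1-based, fully closed (VCF/HGVS convention). Genotype
  phase is ignored (`0/1` ≡ `0|1`); genotype classes are `0/0`, `0/1`,
  `1/1`, missing, and `other` for alleles of a different alternate at a
  split multi-allelic site.
- Multi-allelic records are split so each row carries one alternate; the
  number of (site, alt) pairs is conserved.
- Gene models carry their spliced coding-strand CDS sequence; a variant
  reference allele disagreeing with the model sequence is a hard error,
  never a silent skip, so fixture and input bugs surface immediately.
- HGVS protein changes use one-letter codes by default (`p.E201D`), with
  three-letter rendering as an option. Intronic positions render with
  signed offsets anchored at the nearer exon boundary in transcript sense
  (`c.502+1`, `c.503-1`).
- One transcript model per gene; exonic non-coding (UTR) positions are not
  modelled. Minus-strand genes are handled by counting CDS positions in
  transcript order and complementing alleles; the test suite checks
  minus-strand mapping against an explicitly mirrored plus-strand
  construction.
- BH ties are resolved by the standard min-over-suffix formulation
  (`stats::p.adjust`); the tests cross-check an independently written
  step-up oracle. Hypergeometric tails use `stats::phyper`; the tests
  cross-check exhaustive `choose()` summation for every universe up to 60
  genes.
- CAP class bounds: the printed class table leaves small gaps
  (0.70→0.71, 3.5→3.51, 7.5→7.6, 17.5→17.6); intervals are treated as
  half-open, anchored at the printed lower bounds, with class 5 closed at
  50 — the unique gap-free reading consistent with every printed
  breakpoint. Dust-mite sensitization reads the two-allergen requirement
  conjunctively (both Der f and Der p at class ≥ 2); a disjunctive switch
  exists for sensitivity analysis. Total IgE > 100 kU/l is an annotation
  flag, not an eligibility criterion.

## Problem sizes

The default test suite and the acceptance script run the full scenario
(1000 models, 336 variants, 21 samples, 20,000-gene expression cohort) in
well under a minute per pipeline pass; property suites use reduced sizes
(≤ 50-variant cluster instances, 60-gene enrichment universes, 200-replicate
FDR simulations at 400 genes) chosen so each suite completes in seconds
while still covering the combinatorial space of interest.

## Known limitations

- The strict heterozygous-pair model does not cover recessive inheritance,
  de novo mutations, X-linked special cases, or incomplete genotype data in
  the ascertainment pair.
- Variant-level counting: when a variant is shared by two affected
  children, cascade counts treat it as one variant, not one per pair.
- One transcript per gene; overlapping genes resolve to the first model.
- Enrichment p-values depend strongly on the chosen background; they
  support ranking within a run, not comparison across tools.
- Real per-individual cascade counts from whole-genome data depend on the
  original genomes and databases; the package validates cascade semantics
  on constructed data, not those historical counts.
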