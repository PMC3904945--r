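---
title: "Methods: typing rice hybrid-incompatibility alleles and predicting cross compatibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typing rice hybrid-incompatibility alleles and predicting cross compatibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oryzacompat)
```

## The biology in brief

Three cloned Bateson–Dobzhansky–Muller (BDM) systems contribute to
*indica* × *japonica* hybrid sterility in Asian rice, and this package
models all three:

* **Sa** — adjacent genes *SaM* (SUMO-ligase-like) and *SaF* (F-box)
  on chromosome 1. In an F1 with one functional *SaM+*, one functional
  *SaM−* and at least one *SaF+*, the SaM−-bearing microspores abort:
  male semi-sterility of about 50%.
* **s5** — an aspartic protease on chromosome 6 acting in the embryo
  sac; the *s5-i*/*s5-j* heterodimer reduces spikelet fertility by
  46%, and a 136-bp deletion (*s5-n*) is a wide-compatibility null.
* **DPL** — duplicated genes on chromosomes 1 (*DPL1*) and 6 (*DPL2*)
  expressed in mature anthers; pollen inheriting non-functional copies
  of both (*DPL1-K−* and *DPL2-N−*) is dead.

A fourth element, the 8,628-bp **SaFX** deletion (chromosome 1,
22,371,187–22,379,815 in 1-based end-exclusive coordinates), removes
all of *SaF* and the first four exons of *SaM*. Carriers escape the Sa
interaction; *SaM* alleles in carriers are re-labelled *SaM+X*/*SaM−X*
because most of the gene is gone even though the diagnostic
fifth-intron SNP survives.

## Allele typing

Each locus is typed from a small set of diagnostic polymorphisms held
in a locus definition. Published SNP symbols (C282A, C877T, A434G,
position 287) are coding-sequence coordinates from the original
cloning papers, which do not map directly onto the sequenced amplicons;
operationally every diagnostic is addressed by an **alignment column**
chosen in the built-in configuration, with the published symbol kept as
an annotation. Likewise, which nucleotide state is indica- versus
japonica-type at each SNP is fixed by convention in the configuration
and can be overridden via `load_locus_definitions(config)`.

Classification is a pure function of observed states with three rules:

1. **Deletion precedence.** A sequence with the 136-bp gap is *s5-n*
   whatever its SNP states; a SaFX carrier is *SaFX* at SaF and gets
   the X suffix at SaM.
2. **Decisive remainder.** An `N` or gap at one diagnostic leaves the
   call to the remaining diagnostics when they agree; if none are
   readable the call is missing (excluded from frequency
   denominators).
3. **Conflicts surface.** Diagnostics that disagree (a putative
   recombinant s5 haplotype — the locus has two diagnostic SNPs whose
   reconciliation is not defined anywhere) or contradictory deletion
   evidence (sequence gap but positive amplification) yield a flagged
   conflict call, never a silent resolution.

SaFX itself is genotyped by a complementary primer pair: the SaF
primers amplify only without the deletion, the SaFdel primers only
with it. `detect_safx()` maps the four outcome combinations to
present/absent/missing and treats double success as an assay conflict
(error) and double failure as missing — unexplained amplification
failures do occur and must not be imputed.

## Panel tables

A panel is a long table of allele calls: one row per allele copy.
Wild (*O. rufipogon*) accessions are outcrossing and therefore diploid
— two alleles per locus; cultivated and weedy accessions are selfing
and treated as haploid except for rare heterozygotes, which contribute
two rows. Frequency rows use round-half-up integer percentages, with
the exact percentage kept alongside (printed tables occasionally nudge
a 37.5/62.5 pair to 37/63 so the column sums to 100; the uniform
convention here reproduces any printed cell within one point and the
prose fractions exactly). For s5 the wide-compatibility share is
reported out of indica-type alleles only, since the deletion arises on
indica-type backgrounds.

## Diversity statistics

`segregating_sites()`, `nucleotide_diversity()`, `watterson_theta()`
and `tajimas_d()` follow the common convention of the standard
summary-statistics software: columns containing any gap are excluded
from S, from θ_W's site denominator, and from the complete-deletion
pairwise counts entering Tajima's D; π defaults to pairwise deletion
(each pair compared over its own gap-free sites) and can be switched
to complete deletion. Tajima's D uses the standard constants
(a1, a2, b1, b2, c1, c2, e1, e2) and is undefined — rendered "n/a" —
with fewer than four sequences or no polymorphism. Indel events are
counted as distinct shared gap-run spans, so a 136-bp deletion carried
by many sequences is one event.

Heterozygous wild accessions are phased by Clark haplotype
subtraction (`clark_phase()`): homozygotes seed the known-haplotype
set, each heterozygote compatible with a known haplotype is resolved
by subtraction, and inferred complements join the set until a fixed
point. The algorithm's order dependence is real; heterozygotes are
processed in input order, and records that cannot be resolved are
flagged rather than guessed.

## Genealogies

Haplotype trees are neighbor-joining trees on Kimura two-parameter
distances, d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q), with P and Q the
transition and transversion proportions over the sites where both
sequences have unambiguous bases (pairwise gap deletion, the common
default). Saturated pairs (either log argument non-positive) raise a
typed condition; bootstrap replicates containing a saturated pair are
skipped and the support denominator adjusted. The agglomeration itself
is the standard Saitou–Nei algorithm via `ape::nj()`; negative branch
lengths are clamped to zero with the deficit moved to the adjacent
branches. Bootstrap supports resample alignment columns with
replacement (default B = 500), count bipartition recovery, and are
deterministic under a seed; supports below 50 are hidden when writing
Newick, the usual figure convention.

## The compatibility model

`predict_cross()` forms the F1 per locus (one allele from each parent;
inbred haploid-notation parents are homozygous, diploid parents yield
the 2×2 gamete combinations with their transmission probabilities and
the prediction averages over them) and applies the three system rules:

* Sa: semi-sterile with viable fraction 1 − effect (default effect
  0.5) iff the F1 has exactly one functional *SaM+* and one functional
  *SaM−* plus at least one functional *SaF+*;
* s5: fertility reduction 0.46 iff the F1 is *s5-i*/*s5-j*;
* DPL: viable gamete fraction 1 − P(K−)·P(N−) from the F1's allele
  dosages.

Two modeling choices are deliberately explicit:

* **X alleles are nulls.** SaFX deletes *SaF* entirely and truncates
  *SaM*; the crossing data show no pollen deficit even in a hybrid
  combining a *SaM* heterozygote with *SaF+*, which is exactly what a
  null *SaM+X* predicts. A conservative `x_mode = "unknown"` abstains
  instead of assuming.
* **Systems combine multiplicatively.** The source analyses evaluate
  the systems separately and never state a joint model; the loci sit
  on different chromosomes and act through different mechanisms
  (pollen versus embryo sac), which motivates independence, but the
  product is an assumption, and per-system fractions are always
  reported alongside. How male semi-sterility and embryo-sac abortion
  compose into seed set is genuinely unknown; penetrance variation
  across genetic backgrounds (reported anywhere from 5 to 95%) is not
  modeled.

`population_barrier_matrix()` averages the combined fertility over all
individual × individual crosses per ordered population pair, skipping
untyped systems per cross and reporting how many crosses were partial.

## Pollen statistics

Per individual, percent non-viable pollen is the mean over exactly
three fields of view of 100 · nonviable/(viable + nonviable), and
pollen concentration the mean of three hemacytometer counts times a
chamber conversion factor (the chamber geometry is a configuration
input; only the depth is standardized). Genotype summaries use a
two-level convention taken from the phenotype tables: the mean
averages per-individual values, while the standard deviation pools all
raw measurements. Group comparisons default to Welch's t-test — the
source says only "t-test", and unequal variances are the safer default
— with the pooled Student variant available; whether the original
comparisons used per-individual averages or raw triplicates is
ambiguous, so both granularities are supported.

## The synthetic-data generator

The generator stands in for the deposited GenBank population sets and
defines the study conditions for all tests:

* **Alignments.** Each sequence's diagnostic states are set from its
  truth allele type; the 136-bp s5 deletion and the 517-bp DPL1
  insertion appear as gap blocks; SaFX alleles contribute no sequence
  (whole-amplicon absence) but produce complementary-primer records.
  Neutral variation goes only to non-diagnostic columns, so truth
  labels cannot be corrupted. Variation is organized by haplotype
  class: with a requested haplotype count, sequences are partitioned
  into classes nested within allele types and each class receives a
  distinct presence/absence profile over the segregating sites, which
  realises the requested S (counting segregating diagnostic columns,
  as survey totals do) and haplotype number exactly — e.g. the 89-
  sequence s5 panel with 35 SNPs, 5 indel events and 34 haplotypes.
  Extra indel events are 3-bp class-shared gap runs placed away from
  the deletion blocks.
* **Panels.** `generate_panel_from_marginals()` realises a table of
  per-population allele counts exactly, pairing wild alleles into
  diploid accessions, so frequency tabling reproduces the input
  percentages under the rounding rule by construction.
* **Pollen.** Triplicate fields are drawn around genotype means with
  Gaussian noise (clamped to [0, 100]) and converted to grain counts
  (200 grains scored per field by default, a realistic field-of-view
  total).

What the generator does **not** emulate: coalescent genealogical
structure, recombination, linkage between loci, base-composition or
rate heterogeneity, and sequencing error. Passing tests therefore
demonstrate the correctness of the typing, tabling, statistics and
prediction machinery on panels with known truth — not robustness to
alignment error or model misspecification in real resequencing data,
and not the numeric values of the original diversity tables or tree
figures, which would require the deposited sequences themselves.

## Numerical and design choices

* Intervals are 1-based and end-exclusive, making the SaFX span
  22,379,815 − 22,371,187 = 8,628 exact.
* Integer percentages round half up (`round_half_up()`); R's default
  banker's rounding would turn 62.5 into 62.
* Haplotype ids: the reference (sequenced-genome accession) is
  haplotype 1; the rest order by descending count, ties by first
  appearance — the numbering convention is not specified anywhere, so
  first appearance is fixed here for determinism.
* NJ ties and MEGA-style details (tie-breaking, gap deletion mode for
  distances) are undocumented upstream; pairwise deletion and the
  `ape` implementation's deterministic behaviour are used, and the
  distance gap mode is switchable.
* Tajima's D is reported only for n ≥ 4 sequences with S ≥ 1.
* All randomness flows from explicit integer seeds; generators restore
  the caller's RNG state.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic
data at desk scale, chosen to exercise every code path while keeping a
full run to a few minutes: estimator cross-validation on 200 random
gapped alignments (n ≤ 8, L ≤ 50) against an independent brute-force
oracle; NJ quartet recovery over all three 4-taxon topologies with
random branch lengths; typing truth recovery on 500 alleles per locus;
bootstrap behaviour on an 8-sequence two-clade alignment at B = 100;
and power of the two-genotype pollen design (means 10 vs 40, sd 3,
n = 5) over 200 replicates.

## Known limitations

* The compatibility model predicts relative fertilities, not absolute
  seed set, and ignores F2+ segregation and transmission-ratio
  distortion.
* Clark phasing can fail entirely without a homozygote seed, and its
  output depends on processing order — both properties are surfaced,
  not fixed.
* The frequency-table machinery assumes the closed ten-group panel
  structure; new population labels require extending the group set.
* The Sa effect size ("about 50%") and the X-null hypothesis are
  configurable assumptions, not measured constants.
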