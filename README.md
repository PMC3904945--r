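# oryzacompat

Allele typing at rice hybrid-incompatibility loci and prediction of
crop–weed cross compatibility.

## The problem

Hybrid sterility between the two Asian rice subspecies, *Oryza sativa*
ssp. *indica* and ssp. *japonica*, is driven in part by three cloned
Bateson–Dobzhansky–Muller (BDM) systems:

- **Sa** (chromosome 1, pollen): two adjacent genes, *SaM* and *SaF*.
  An F1 carrying a functional *SaM+*/*SaM−* heterozygote together with
  at least one functional *SaF+* allele selectively aborts the
  *SaM−*-bearing microspores — male semi-sterility of roughly 50%.
- **s5** (chromosome 6, embryo sac): the *s5-i*/*s5-j* heterodimer
  causes embryo-sac abortion, reducing spikelet fertility by 46%. A
  136-bp deletion (*s5-n*) is a null, wide-compatibility allele.
- **DPL** (chromosomes 1 and 6, pollen): duplicate genes *DPL1*/*DPL2*.
  Pollen carrying non-functional alleles at both (*DPL1-K−* with
  *DPL2-N−*) is non-viable; with independent assortment the viable
  gamete fraction of an F1 follows by enumerating the four gamete
  classes (a double heterozygote keeps 1 − ¼ = 0.75).

US rice fields are planted with *japonica*-derived cultivars but
invaded by *indica*/*aus*-derived weedy ("red") rice — groups SH, BHA1,
BHA2, plus the hybrid-derived BRH and MX. Whether these BDM systems
impede crop–weed gene flow depends on which alleles each group carries.
A key player is **SaFX**, an 8,628-bp deletion (chromosome 1 positions
22,371,187–22,379,815, end-exclusive) that removes all of *SaF* and the
first four exons of *SaM*, behaving as a compatibility-restoring null;
*SaM* alleles in SaFX carriers are written *SaM+X*/*SaM−X*.

The package implements the full analysis around these systems:

- diagnostic-polymorphism allele typing at all five genes from gapped
  FASTA alignments and complementary-primer assays
  (`load_locus_definitions()`, `classify_allele()`, `detect_safx()`,
  `type_alignment()`);
- population allele-type frequency tables and two-locus genotype
  distributions (`build_panel()`, `allele_type_frequencies()`,
  `genotype_distribution()`, `render_table1()`);
- diversity statistics per population × locus — segregating sites,
  nucleotide diversity π, Watterson's θ_W, Tajima's D, haplotype and
  indel counts — and Clark haplotype-subtraction phasing
  (`diversity_stats()`, `clark_phase()`);
- neighbor-joining haplotype genealogies under the Kimura
  two-parameter model with bootstrap supports (`k2p_distance()`,
  `nj_tree()`, `bootstrap_supports()`);
- the BDM sterility rules and cross predictions (`evaluate_sa()`,
  `evaluate_s5()`, `evaluate_dpl()`, `predict_cross()`,
  `population_barrier_matrix()`);
- pollen phenotype statistics (`nonviable_percent()`,
  `pollen_concentration()`, `genotype_summary()`, `two_sample_t()`);
- a synthetic-data module generating aligned panels, genotype tables
  and pollen datasets with full ground truth (`generate_alignment()`,
  `generate_panel_from_marginals()`, `generate_pollen_dataset()`).

## Worked example

```r
library(oryzacompat)

# the SaFX deletion span from its breakpoints, via the primer assay
detect_safx("fail", "success", breakpoints = c(22371187, 22379815))$span_bp
#> [1] 8628

# an SH weed typical genotype crossed to a US japonica cultivar
predict_cross("s5-n;SaM+X/SaFX;DPL1-N+;DPL2-K+",
              "s5-j;SaM-/SaF-;DPL1-N+;DPL2-K+")
#> Cross prediction
#>   Sa   compatible   viable fraction 1
#>   s5   compatible   viable fraction 1
#>   DPL  compatible   viable fraction 1
#>   combined relative fertility: 1

# the canonical indica x japonica cross is semi-sterile at two systems
predict_cross("s5-i;SaM+/SaF+;DPL1-K-;DPL2-K+",
              "s5-j;SaM-/SaF-;DPL1-N+;DPL2-K+")
#> Cross prediction
#>   Sa   semi-sterile viable fraction 0.5
#>   s5   semi-sterile viable fraction 0.54
#>   DPL  compatible   viable fraction 1
#>   combined relative fertility: 0.27
```

The combined relative fertility is the product of the per-system
viable fractions (0.5 × 0.54 × 1 = 0.27): the SH weed can hybridize
freely with the local crop, while a typical *indica* × *japonica*
cross loses about three quarters of its expected fertility.

## Analysis workflow

The `analysis/` scripts re-run the study end to end on synthetic data
(the deposited GenBank sequences are not required):

1. `01_simulate_panel.R` — simulate the 10-population genotype panel
   from the survey's marginal allele counts, per-locus alignments
   matched to the reported segregating-site/indel/haplotype summaries
   (e.g. 34 s5 haplotypes, 35 SNPs), primer records and pollen data.
2. `02_type_and_tabulate.R` — type every sequence, build the frequency
   table, genotype distributions, diversity table, NJ trees
   (500-replicate-style bootstrap, here B = 100) and barrier matrix
   via `run_pipeline()`.
3. `03_cross_predictions.R` — predict the verified test crosses and
   population-level compatibility.
4. `04_pollen_phenotypes.R` — genotype summaries of pollen quality and
   the SaFX-carrier comparison.

Outputs land under `results/`.

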