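#!/usr/bin/env Rscript
# Simulate the study panel: a genotype table whose per-population
# allele-type counts follow the reported survey marginals, plus aligned
# haplotype panels per sequenced locus matched to the reported
# segregating-site / indel / haplotype summaries, the complementary
# SaFX primer records, and triplicate pollen measurements. Everything
# is written under results/data with full ground truth.

suppressPackageStartupMessages(library(oryzacompat))
seed <- 20140128 %% 2^31
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Per-population allele-type counts (alleles, not individuals), as
## tallied in the survey: ten Oryza groups across the five loci.
marginals <- rbind(
  # s5 --- wide-compatibility deletion prominent in weeds and aus
  data.frame(group = "indica",   locus = "s5", allele = "s5-i", count = 6),
  data.frame(group = "aus",      locus = "s5", allele = "s5-n", count = 3),
  data.frame(group = "japonica", locus = "s5",
             allele = c("s5-n", "s5-j"), count = c(3, 5)),
  data.frame(group = "SH",  locus = "s5",
             allele = c("s5-n", "s5-i"), count = c(12, 2)),
  data.frame(group = "BHA1", locus = "s5", allele = "s5-n", count = 14),
  data.frame(group = "BHA2", locus = "s5",
             allele = c("s5-n", "s5-i", "s5-j"), count = c(4, 1, 3)),
  data.frame(group = "MX",  locus = "s5", allele = "s5-n", count = 5),
  data.frame(group = "BRH", locus = "s5", allele = "s5-n", count = 4),
  data.frame(group = "wild", locus = "s5",
             allele = c("s5-i", "s5-n", "s5-j"), count = c(25, 4, 1)),
  # DPL1 --- insertion (K-) common in indica/aus-derived groups
  data.frame(group = "indica", locus = "DPL1",
             allele = c("DPL1-K-", "DPL1-N+"), count = c(4, 2)),
  data.frame(group = "aus",  locus = "DPL1", allele = "DPL1-K-", count = 5),
  data.frame(group = "japonica", locus = "DPL1",
             allele = c("DPL1-K-", "DPL1-N+"), count = c(3, 11)),
  data.frame(group = "SH",   locus = "DPL1", allele = "DPL1-N+", count = 11),
  data.frame(group = "BHA1", locus = "DPL1",
             allele = c("DPL1-K-", "DPL1-N+"), count = c(10, 3)),
  data.frame(group = "BHA2", locus = "DPL1", allele = "DPL1-K-", count = 7),
  data.frame(group = "MX",   locus = "DPL1", allele = "DPL1-N+", count = 5),
  data.frame(group = "BRH",  locus = "DPL1",
             allele = c("DPL1-K-", "DPL1-N+"), count = c(1, 3)),
  data.frame(group = "wild", locus = "DPL1",
             allele = c("DPL1-K-", "DPL1-N+"), count = c(14, 18)),
  # DPL2 --- the nonfunctional N- allele is rare everywhere
  data.frame(group = "indica", locus = "DPL2", allele = "DPL2-K+", count = 4),
  data.frame(group = "aus",    locus = "DPL2", allele = "DPL2-K+", count = 4),
  data.frame(group = "japonica", locus = "DPL2",
             allele = c("DPL2-K+", "DPL2-N-"), count = c(11, 2)),
  data.frame(group = "SH",   locus = "DPL2", allele = "DPL2-K+", count = 13),
  data.frame(group = "BHA1", locus = "DPL2", allele = "DPL2-K+", count = 13),
  data.frame(group = "BHA2", locus = "DPL2", allele = "DPL2-K+", count = 9),
  data.frame(group = "MX",   locus = "DPL2",
             allele = c("DPL2-K+", "DPL2-N-"), count = c(4, 1)),
  data.frame(group = "BRH",  locus = "DPL2", allele = "DPL2-K+", count = 3),
  data.frame(group = "wild", locus = "DPL2", allele = "DPL2-K+", count = 28),
  # SaM --- X-suffixed alleles ride on the SaFX deletion
  data.frame(group = "indica", locus = "SaM",
             allele = c("SaM+", "SaM-"), count = c(8, 1)),
  data.frame(group = "aus", locus = "SaM",
             allele = c("SaM+", "SaM-"), count = c(4, 1)),
  data.frame(group = "japonica", locus = "SaM",
             allele = c("SaM+", "SaM-"), count = c(1, 9)),
  data.frame(group = "SH", locus = "SaM",
             allele = c("SaM+", "SaM-", "SaM+X", "SaM-X"),
             count = c(2, 1, 12, 1)),
  data.frame(group = "BHA1", locus = "SaM", allele = "SaM+", count = 15),
  data.frame(group = "BHA2", locus = "SaM",
             allele = c("SaM+", "SaM-"), count = c(8, 1)),
  data.frame(group = "MX", locus = "SaM",
             allele = c("SaM+", "SaM-"), count = c(4, 1)),
  data.frame(group = "BRH", locus = "SaM",
             allele = c("SaM+", "SaM+X", "SaM-X"), count = c(1, 3, 1)),
  data.frame(group = "wild", locus = "SaM",
             allele = c("SaM+", "SaM-", "SaM+X"), count = c(25, 7, 6)),
  # SaF --- SaFX nearly fixed in SH and BRH
  data.frame(group = "indica", locus = "SaF",
             allele = c("SaF+", "SaF-"), count = c(7, 2)),
  data.frame(group = "aus", locus = "SaF",
             allele = c("SaF+", "SaF-"), count = c(6, 1)),
  data.frame(group = "japonica", locus = "SaF", allele = "SaF-", count = 8),
  data.frame(group = "SH", locus = "SaF",
             allele = c("SaF-", "SaFX"), count = c(1, 13)),
  data.frame(group = "BHA1", locus = "SaF", allele = "SaF+", count = 15),
  data.frame(group = "BHA2", locus = "SaF",
             allele = c("SaF+", "SaF-"), count = c(7, 1)),
  data.frame(group = "MX", locus = "SaF",
             allele = c("SaF+", "SaF-"), count = c(4, 1)),
  data.frame(group = "BRH", locus = "SaF", allele = "SaFX", count = 4),
  data.frame(group = "wild", locus = "SaF",
             allele = c("SaF+", "SaF-", "SaFX"), count = c(17, 19, 8)))

panel <- generate_panel_from_marginals(marginals, seed = seed)
write.table(panel$metadata, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(panel$calls, file.path(out, "calls_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("panel: %d accessions, %d allele calls\n",
            nrow(panel$metadata), nrow(panel$calls)))

## Aligned haplotype panels per sequenced locus, matched to the
## reported alignment summaries (S, indel events, haplotype numbers).
## DPL1 is assayed by gel size only, so no alignment is generated.
aln_specs <- list(
  s5   = list(counts = c("s5-i" = 34, "s5-n" = 46, "s5-j" = 9),
              S = 35, indels = 4, haps = 34),
  DPL2 = list(counts = c("DPL2-K+" = 89, "DPL2-N-" = 3),
              S = 22, indels = 4, haps = 9),
  SaM  = list(counts = c("SaM+" = 68, "SaM-" = 21, "SaM+X" = 21,
                         "SaM-X" = 2),
              S = 20, indels = 7, haps = 20),
  SaF  = list(counts = c("SaF+" = 56, "SaF-" = 33, "SaFX" = 25),
              S = 24, indels = 1, haps = 18))
amp_all <- list()
for (loc in names(aln_specs)) {
  sp <- aln_specs[[loc]]
  g <- generate_alignment(loc, sp$counts, seed = seed + match(loc, names(aln_specs)),
                          target_S = sp$S, n_indels = sp$indels,
                          n_haplotypes = sp$haps)
  write_alignment(g$alignment, file.path(out, paste0(loc, ".fa")))
  write.table(g$truth, file.path(out, paste0(loc, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(g$amp_calls)) amp_all[[loc]] <- g$amp_calls
  cat(sprintf("%s: %d sequences, %d haplotypes, S = %d, indel events = %d\n",
              loc, nrow(g$alignment),
              nrow(enumerate_haplotypes(g$alignment)),
              segregating_sites(g$alignment), count_indels(g$alignment)))
}
write.table(do.call(rbind, unname(amp_all)),
            file.path(out, "amp_calls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## Pollen measurements around the per-genotype means seen in the
## crossing experiment (percent non-viable pollen).
effects <- c("SaM+/SaF+" = 7.7, "SaM-/SaF-" = 16.7, "SaM+/SaF-" = 5.6,
             "SaM+X/SaFX" = 8.25, "SaM-X/SaFX" = 25.4)
pollen <- generate_pollen_dataset(effects, noise_sd = 5,
                                  n_per_genotype = setNames(c(3, 4, 2, 4, 2),
                                                            names(effects)),
                                  seed = seed + 9)
write.table(pollen, file.path(out, "pollen.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("pollen: %d individuals x 3 fields\n",
            length(unique(pollen$accession))))
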