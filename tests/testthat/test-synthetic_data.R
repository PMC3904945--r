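test_that("alignment generation is deterministic and honors its composition", {
  g1 <- generate_alignment("s5", c("s5-j" = 5, "s5-i" = 3), seed = 21,
                           target_S = 12, n_indels = 2)
  g2 <- generate_alignment("s5", c("s5-j" = 5, "s5-i" = 3), seed = 21,
                           target_S = 12, n_indels = 2)
  expect_identical(g1, g2)

  # typing recovers exactly the requested 5/3 split
  defs <- load_locus_definitions()
  calls <- type_alignment(defs$s5, g1$alignment)
  types <- vapply(calls, `[[`, "", "allele_type")
  expect_equal(sum(types == "s5-j"), 5L)
  expect_equal(sum(types == "s5-i"), 3L)

  # with no neutral variation, same-type sequences are identical
  g0 <- generate_alignment("s5", c("s5-j" = 4, "s5-n" = 3), seed = 2)
  h <- enumerate_haplotypes(g0$alignment)
  expect_equal(nrow(h), 2L)

  # requested haplotype count is reached exactly
  g34 <- generate_alignment("s5", c("s5-i" = 20, "s5-j" = 14), seed = 9,
                            target_S = 20, n_haplotypes = 34)
  expect_equal(nrow(enumerate_haplotypes(g34$alignment)), 34L)

  # impossible targets rejected
  expect_error(generate_alignment("DPL2", c("DPL2-K+" = 4), seed = 1,
                                  target_S = 10000),
               "exceed")
})

test_that("generated truth labels always round-trip through the classifier", {
  defs <- load_locus_definitions()
  specs <- list(
    s5 = c("s5-i" = 10, "s5-j" = 10, "s5-n" = 10),
    DPL1 = c("DPL1-N+" = 15, "DPL1-K-" = 15),
    DPL2 = c("DPL2-K+" = 20, "DPL2-N-" = 10),
    SaM = c("SaM+" = 10, "SaM-" = 10, "SaM+X" = 5, "SaM-X" = 5),
    SaF = c("SaF+" = 12, "SaF-" = 12, "SaFX" = 6))
  for (loc in names(specs)) {
    g <- generate_alignment(loc, specs[[loc]], seed = 17, target_S = 8,
                            n_indels = 1)
    calls <- type_alignment(defs[[loc]], g$alignment,
                            safx_carriers = g$safx_carriers)
    got <- vapply(calls, `[[`, "", "allele_type")
    truth <- g$truth[!g$truth$allele_type %in% "SaFX", ]
    truth <- setNames(truth$allele_type, truth$seq_id)
    # SaM X alleles need the assay flag, sequences for them exist
    expect_equal(got[names(truth)], truth, ignore_attr = TRUE)
    # SaFX alleles carry no sequence but a complementary-primer record
    if (loc == "SaF") {
      expect_equal(length(g$safx_carriers), 6L)
      amp <- g$amp_calls
      for (acc in g$safx_carriers) {
        saf <- amp$outcome[amp$accession == acc & amp$primer_set == "SaF"]
        dele <- amp$outcome[amp$accession == acc & amp$primer_set == "SaFdel"]
        expect_true(detect_safx(saf, dele)$present)
      }
    }
  }
})

test_that("whole-locus amplification failures are simulated and tracked", {
  g <- generate_alignment("DPL2", c("DPL2-K+" = 40, "DPL2-N-" = 10),
                          seed = 5, missing_rate = 0.2)
  expect_true(any(g$truth$missing))
  expect_false(any(g$truth$seq_id[g$truth$missing] %in%
                     rownames(g$alignment)))
})

test_that("panels from marginal counts reproduce the input percentages exactly", {
  # wild s5: 29 indica-type of 30
  counts <- data.frame(group = "wild", locus = "s5",
                       allele = c("s5-i", "s5-n", "s5-j"),
                       count = c(25, 4, 1))
  p <- generate_panel_from_marginals(counts, seed = 8)
  fr <- allele_type_frequencies(p$panel, "s5", "wild")
  expect_equal(attr(fr, "indica_type_percent"), 97)

  # SaM wild counts {25 SaM+, 6 SaM+X, 7 SaM-}: indica-like 31/38 -> 82
  counts <- data.frame(group = "wild", locus = "SaM",
                       allele = c("SaM+", "SaM+X", "SaM-"),
                       count = c(25, 6, 7))
  p <- generate_panel_from_marginals(counts, seed = 8)
  fr <- allele_type_frequencies(p$panel, "SaM", "wild")
  ind_like <- sum(fr$count[fr$allele_type %in% c("SaM+", "SaM+X")])
  expect_equal(ind_like, 31L)
  expect_equal(percent_of(ind_like, attr(fr, "n_alleles"))$percent, 82L)

  # determinism and the empty-group case
  p2 <- generate_panel_from_marginals(counts, seed = 8)
  expect_identical(p$panel, p2$panel)
  empty <- data.frame(group = "aus", locus = "s5", allele = "s5-i",
                      count = 0)
  p0 <- generate_panel_from_marginals(empty, seed = 1)
  expect_equal(nrow(p0$calls), 0L)

  expect_error(generate_panel_from_marginals(
    data.frame(group = "SH", locus = "s5", allele = "s5-i", count = -1),
    seed = 1), "negative")
  expect_error(generate_panel_from_marginals(
    data.frame(group = "SH", locus = "s5", allele = "bogus", count = 1),
    seed = 1), "enumeration")
})

test_that("pollen datasets carry their truth and respond to noise settings", {
  eff <- c("SaM+/SaF-" = 10, "SaM-/SaF-" = 40)

  # sd = 0: recovered per-individual means equal the truth
  d <- generate_pollen_dataset(eff, noise_sd = 0, n_per_genotype = 3,
                               seed = 6)
  for (acc in unique(d$accession)) {
    sub <- d[d$accession == acc, ]
    expect_equal(nonviable_percent(sub), sub$true_mean[1])
  }

  # n = 0 for a genotype: absent from the output
  d <- generate_pollen_dataset(eff, noise_sd = 1,
                               n_per_genotype = c("SaM+/SaF-" = 2,
                                                  "SaM-/SaF-" = 0),
                               seed = 6)
  expect_false("SaM-/SaF-" %in% d$genotype)

  # deterministic under seed
  d1 <- generate_pollen_dataset(eff, 3, 5, seed = 99)
  d2 <- generate_pollen_dataset(eff, 3, 5, seed = 99)
  expect_identical(d1, d2)
  expect_error(generate_pollen_dataset(c(g = 120), 1, 1, seed = 1))
})

test_that("generator output files are byte-identical under a fixed seed", {
  g <- generate_alignment("SaM", c("SaM+" = 6, "SaM-" = 6), seed = 44,
                          target_S = 5)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_alignment(g$alignment, f1)
  g2 <- generate_alignment("SaM", c("SaM+" = 6, "SaM-" = 6), seed = 44,
                           target_S = 5)
  write_alignment(g2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and FASTA round-trips through the reader
  expect_equal(read_alignment(f1), g$alignment)
})
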