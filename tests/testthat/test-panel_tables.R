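test_that("panel assembly validates groups, accessions and allele labels", {
  meta <- data.frame(accession = c("a1", "a2", "w1"),
                     group = c("indica", "SH", "wild"),
                     stringsAsFactors = FALSE)
  calls <- data.frame(accession = c("a1", "a2", "w1", "w1"),
                      locus = c("s5", "s5", "SaM", "SaM"),
                      allele = c("s5-i", "s5-n", "SaM+", "SaM-"),
                      stringsAsFactors = FALSE)
  panel <- build_panel(meta, calls)
  expect_s3_class(panel, "hi_panel")
  # diploid wild record carries both alleles
  expect_equal(sort(panel$allele[panel$accession == "w1"]),
               c("SaM+", "SaM-"))
  expect_true(all(panel$diploid[panel$accession == "w1"]))

  expect_error(build_panel(rbind(meta, meta[1, ]), calls), "duplicate")
  expect_error(build_panel(within(meta, group[1] <- "altica"), calls),
               "unknown group")
  expect_error(build_panel(meta, within(calls, accession[1] <- "zz")),
               "absent from metadata")
  expect_error(build_panel(meta, within(calls, allele[1] <- "s5-x")),
               "enumeration")
})

test_that("allele-type frequencies reproduce the printed fraction arithmetic", {
  # 8 japonica s5 alleles, 3 indica-type (all plain s5-i), 5 japonica-type
  counts <- data.frame(group = "japonica", locus = "s5",
                       allele = c("s5-i", "s5-j"), count = c(3, 5))
  p <- generate_panel_from_marginals(counts, seed = 1)
  fr <- allele_type_frequencies(p$panel, "s5", "japonica")
  expect_equal(fr$percent[fr$allele_type == "s5-j"], 63)     # table rounding
  expect_equal(fr$percent_raw[fr$allele_type == "s5-j"], 62.5)  # prose value
  # 3/8 = 37.5 rounds half-up to 38 (printed tables nudge the pair to
  # sum to 100; the convention here is uniform round-half-up, within
  # one point of any printed cell)
  expect_equal(attr(fr, "indica_type_percent"), 38)

  # 30 wild s5 alleles, 29 indica-type (incl. wc carriers)
  counts <- data.frame(group = "wild", locus = "s5",
                       allele = c("s5-i", "s5-n", "s5-j"),
                       count = c(25, 4, 1))
  p <- generate_panel_from_marginals(counts, seed = 1)
  fr <- allele_type_frequencies(p$panel, "s5", "wild")
  expect_equal(attr(fr, "indica_type_percent"), 97)
  # wc share computed out of indica-type alleles only: 4/29 -> 14
  expect_equal(attr(fr, "wc_percent"), 14)

  # all one type
  counts <- data.frame(group = "SH", locus = "DPL2",
                       allele = "DPL2-K+", count = 10)
  p <- generate_panel_from_marginals(counts, seed = 1)
  fr <- allele_type_frequencies(p$panel, "DPL2", "SH")
  expect_equal(fr$percent[fr$allele_type == "DPL2-K+"], 100)
  expect_equal(fr$percent[fr$allele_type == "DPL2-N-"], 0)

  # zero denominator: explicit empty result, not zero percentages
  fr0 <- allele_type_frequencies(p$panel, "DPL2", "aus")
  expect_equal(nrow(fr0), 0L)
  expect_equal(attr(fr0, "n_alleles"), 0L)
})

test_that("frequencies are order-invariant and counts partition the denominator", {
  counts <- data.frame(group = "BHA1", locus = "SaM",
                       allele = c("SaM+", "SaM-"), count = c(11, 4))
  p <- generate_panel_from_marginals(counts, seed = 3)
  fr1 <- allele_type_frequencies(p$panel, "SaM", "BHA1")
  shuffled <- p$panel[rev(seq_len(nrow(p$panel))), ]
  class(shuffled) <- class(p$panel)
  fr2 <- allele_type_frequencies(shuffled, "SaM", "BHA1")
  expect_equal(fr1$percent, fr2$percent)
  expect_equal(sum(fr1$count), attr(fr1, "n_alleles"))

  # missing calls reduce the denominator
  calls <- data.frame(accession = sprintf("x%02d", 1:10), locus = "SaM",
                      allele = c(rep("SaM+", 8), NA, NA))
  meta <- data.frame(accession = sprintf("x%02d", 1:10), group = "MX")
  panel <- build_panel(meta, calls)
  fr <- allele_type_frequencies(panel, "SaM", "MX")
  expect_equal(attr(fr, "n_alleles"), 8L)
  expect_equal(attr(fr, "n_missing"), 2L)
})

test_that("estimated frequencies converge to generating probabilities", {
  # n = 500 alleles drawn with known type probabilities
  set.seed(99)
  probs <- c("SaF+" = 0.6, "SaF-" = 0.3, "SaFX" = 0.1)
  draws <- sample(names(probs), 500, replace = TRUE, prob = probs)
  counts <- data.frame(group = "wild", locus = "SaF",
                       allele = names(probs),
                       count = as.vector(table(draws)[names(probs)]))
  p <- generate_panel_from_marginals(counts, seed = 7)
  fr <- allele_type_frequencies(p$panel, "SaF", "wild")
  for (t in names(probs)) {
    se <- sqrt(probs[[t]] * (1 - probs[[t]]) / 500)
    expect_lt(abs(fr$percent_raw[fr$allele_type == t] / 100 - probs[[t]]),
              3 * se)
  }
})

test_that("joint genotype distributions tally haploid classes and report exclusions", {
  # SH fixed for the functional double genotype
  meta <- data.frame(accession = sprintf("sh%02d", 1:11), group = "SH")
  calls <- rbind(
    data.frame(accession = meta$accession, locus = "DPL1",
               allele = "DPL1-N+"),
    data.frame(accession = meta$accession, locus = "DPL2",
               allele = "DPL2-K+"))
  panel <- build_panel(meta, calls)
  d <- genotype_distribution(panel, c("DPL1", "DPL2"), "SH")
  expect_equal(d$genotype, "DPL1-N+/DPL2-K+")
  expect_equal(d$percent, 100)

  # wild panel with exactly two joint classes
  meta <- data.frame(accession = sprintf("w%02d", 1:12), group = "wild")
  calls <- rbind(
    data.frame(accession = meta$accession, locus = "DPL1",
               allele = rep(c("DPL1-K-", "DPL1-N+"), times = c(5, 7))),
    data.frame(accession = meta$accession, locus = "DPL2",
               allele = "DPL2-K+"))
  panel <- build_panel(meta, calls)
  d <- genotype_distribution(panel, c("DPL1", "DPL2"), "wild")
  expect_setequal(d$genotype,
                  c("DPL1-K-/DPL2-K+", "DPL1-N+/DPL2-K+"))

  # empty group
  d0 <- genotype_distribution(panel, c("DPL1", "DPL2"), "aus")
  expect_equal(nrow(d0), 0L)

  # one locus missing: excluded and tallied
  calls$allele[calls$accession == "w01" & calls$locus == "DPL2"] <- NA
  panel <- build_panel(meta, calls)
  d <- genotype_distribution(panel, c("DPL1", "DPL2"), "wild")
  expect_equal(attr(d, "excluded"), 1L)
  expect_equal(sum(d$count), 11L)

  # a heterozygote is written out as a full diploid genotype
  meta <- data.frame(accession = "h1", group = "MX")
  calls <- data.frame(accession = "h1",
                      locus = c("SaM", "SaM", "SaF", "SaF"),
                      allele = c("SaM+X", "SaM-", "SaFX", "SaF-"))
  panel <- build_panel(meta, calls)
  d <- genotype_distribution(panel, c("SaM", "SaF"), "MX")
  expect_equal(d$genotype, "SaM+X/SaM-//SaF-/SaFX")
})

test_that("the rendered frequency table keeps fixed group order and the wc row", {
  counts <- rbind(
    data.frame(group = "japonica", locus = "s5",
               allele = c("s5-i", "s5-j"), count = c(3, 5)),
    data.frame(group = "SH", locus = "s5",
               allele = c("s5-i", "s5-n"), count = c(2, 12)),
    data.frame(group = "SH", locus = "DPL1",
               allele = "DPL1-N+", count = 11))
  p <- generate_panel_from_marginals(counts, seed = 5)
  tab <- render_table1(p$panel, loci = c("s5", "DPL1"))
  expect_equal(setdiff(names(tab), c("locus", "row")),
               c("indica", "aus", "japonica", "SH", "BHA1", "BHA2",
                 "MX", "BRH", "wild"))
  s5_block <- tab[tab$locus == "s5", ]
  expect_true("wc" %in% s5_block$row)
  # groups with no data render as empty cells, not dropped columns
  expect_true(all(s5_block$indica == ""))
  # wc out of indica-type alleles: 12/14 -> 86
  expect_equal(s5_block$SH[s5_block$row == "wc"], "86")
  expect_equal(s5_block$japonica[s5_block$row == "s5-j"], "63")
})
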