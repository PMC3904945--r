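test_that("built-in locus definitions cover the five genes with their diagnostics", {
  defs <- load_locus_definitions()
  expect_named(defs, c("s5", "DPL1", "DPL2", "SaM", "SaF"))

  s5 <- defs$s5
  snps <- Filter(function(d) d$kind == "SNP", s5$diagnostics)
  expect_length(snps, 2L)
  expect_equal(s5$deletion_defs[[1]]$length, 136L)

  expect_equal(defs$DPL1$diagnostics[[1]]$indel_length, 517L)
  expect_error(load_locus_definitions(list(Sb = list(length = 100L))),
               "Sb")
  # inconsistent breakpoints rejected
  expect_error(load_locus_definitions(list(
    SaF = list(deletion_defs = list(list(
      name = "SaFX", length = 100L, start = 1L, end = 50L,
      detection_mode = "complementary-primer-amplification"))))),
    "does not equal length")
})

test_that("classification maps diagnostic states to allele types with deletion precedence", {
  defs <- load_locus_definitions()

  # deletion precedence over SNP states at s5
  del <- classify_allele(defs$s5, list(states = c(C282A = "A", C877T = "T"),
                                       deletions = c("s5-n" = TRUE)))
  expect_equal(del$allele_type, "s5-n")
  # even on a japonica SNP background
  del2 <- classify_allele(defs$s5, list(states = c(C282A = "C", C877T = "C"),
                                        deletions = c("s5-n" = TRUE)))
  expect_equal(del2$allele_type, "s5-n")

  # plain SNP typing
  ii <- classify_allele(defs$s5, list(states = c(C282A = "A", C877T = "T")))
  expect_equal(ii$allele_type, "s5-i")
  jj <- classify_allele(defs$s5, list(states = c(C282A = "C", C877T = "C")))
  expect_equal(jj$allele_type, "s5-j")

  # DPL1 insertion absence is the functional type
  np <- classify_allele(defs$DPL1, list(states = c(ins517 = "absent")))
  expect_equal(np$allele_type, "DPL1-N+")
  km <- classify_allele(defs$DPL1, list(states = c(ins517 = "present")))
  expect_equal(km$allele_type, "DPL1-K-")

  # SaM re-assignment in a SaFX carrier
  px <- classify_allele(defs$SaM, list(states = c(intron5_G_T = "G"),
                                       deletions = c(SaFX = TRUE)))
  expect_equal(px$allele_type, "SaM+X")
  mx <- classify_allele(defs$SaM, list(states = c(intron5_G_T = "T"),
                                       deletions = c(SaFX = TRUE)))
  expect_equal(mx$allele_type, "SaM-X")
  # SaF in a carrier is SaFX regardless of any residual SNP read
  fx <- classify_allele(defs$SaF, list(states = c(C287T = "C"),
                                       deletions = c(SaFX = TRUE)))
  expect_equal(fx$allele_type, "SaFX")
})

test_that("ambiguous and conflicting evidence is surfaced, not resolved", {
  defs <- load_locus_definitions()

  # N at one s5 SNP: the other is decisive
  one <- classify_allele(defs$s5, list(states = c(C282A = "N", C877T = "T")))
  expect_equal(one$allele_type, "s5-i")
  expect_false(one$missing)
  # both unreadable: missing
  none <- classify_allele(defs$s5, list(states = c(C282A = "N", C877T = "N")))
  expect_true(none$missing)
  expect_true(is.na(none$allele_type))

  # recombinant s5 haplotype (SNPs disagree): conflict
  rec <- classify_allele(defs$s5, list(states = c(C282A = "A", C877T = "C")))
  expect_true(rec$conflict)
  expect_true(is.na(rec$allele_type))

  # invalid state rejected
  expect_error(classify_allele(defs$s5,
                               list(states = c(C282A = "Z", C877T = "C"))),
               "outside")

  # classification is a pure function
  obs <- list(states = c(C282A = "A", C877T = "T"))
  expect_identical(classify_allele(defs$s5, obs),
                   classify_allele(defs$s5, obs))
})

test_that("the complementary-primer SaFX assay resolves presence, absence and conflicts", {
  expect_true(detect_safx("fail", "success")$present)
  expect_false(detect_safx("success", "fail")$present)
  expect_false(detect_safx("success", NA)$present)
  expect_true(is.na(detect_safx("fail", "fail")$present))
  expect_equal(detect_safx("fail", "fail")$status, "missing")
  expect_error(detect_safx("success", "success"), "conflict")
  expect_error(detect_safx(), "at least one")

  # deletion span from the genomic breakpoints (1-based, end-exclusive)
  r <- detect_safx("fail", "success", breakpoints = c(22371187, 22379815))
  expect_identical(r$span_bp, 8628)
})

test_that("haplotype enumeration collapses identical sequences and numbers the reference 1", {
  aln <- c(ref = "ACGTACGTAC",
           a = "ACGAACGTAC", b = "ACGAACGTAC",
           c = "ACGAACGTAC", d = "ACGAACGTAC")
  h <- enumerate_haplotypes(aln, reference_id = "ref")
  expect_equal(nrow(h), 2L)
  expect_equal(h$count[h$haplotype_id == 1], 1L)   # reference, despite rarity
  expect_equal(h$count[h$haplotype_id == 2], 4L)

  # a single 1-bp gap separates haplotypes
  g <- c(x = "ACGTACGTAC", y = "ACGTAC-TAC")
  expect_equal(nrow(enumerate_haplotypes(g)), 2L)

  # partition property: counts sum to n, over random inputs
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    aln <- random_alignment(n, 20)
    h <- enumerate_haplotypes(aln)
    expect_equal(sum(h$count), n)
    expect_setequal(unlist(h$members), rownames(aln))
  }

  # ids after the reference follow descending count
  set.seed(1)
  aln <- random_alignment(8, 15, gap_prob = 0)
  h <- enumerate_haplotypes(aln)
  expect_true(all(diff(h$count) <= 0))

  expect_error(enumerate_haplotypes(c(a = "ACGT", b = "ACG")), "mismatch")
  expect_error(enumerate_haplotypes(character()), "empty")
  expect_error(enumerate_haplotypes(c(a = "ACGT"), reference_id = "zz"),
               "not in alignment")
})

test_that("typing an alignment applies external SaFX flags and gap evidence", {
  defs <- load_locus_definitions()
  g <- generate_alignment("SaM", c("SaM+" = 2, "SaM-" = 2), seed = 11)
  # mark the first sequence as a SaFX carrier via the assay
  carrier <- rownames(g$alignment)[1]
  calls <- type_alignment(defs$SaM, g$alignment, safx_carriers = carrier)
  expect_equal(calls[[carrier]]$allele_type, "SaM+X")
  others <- setdiff(rownames(g$alignment), carrier)
  expect_false(any(grepl("X", vapply(calls[others], `[[`, "", "allele_type"))))
})
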