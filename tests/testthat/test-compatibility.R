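test_that("F1 genotypes combine one allele per parent, symmetrically", {
  # the SaFX test cross: (SaM+X/SaFX) x (SaM-/SaF-)
  f1 <- f1_genotype("SaM+X/SaFX", "SaM-/SaF-")
  expect_equal(f1$combos$SaM, list(c("SaM+X", "SaM-")))
  expect_equal(f1$combos$SaF, list(c("SaF-", "SaFX")))

  # homozygote self-cross
  f1 <- f1_genotype("s5-i", "s5-i")
  expect_equal(f1$combos$s5, list(c("s5-i", "s5-i")))

  f1 <- f1_genotype("s5-i", "s5-n")
  expect_equal(f1$combos$s5, list(c("s5-i", "s5-n")))

  # symmetry
  a <- "s5-i;SaM+/SaF+"; b <- "s5-j;SaM-/SaF-"
  expect_equal(f1_genotype(a, b)$combos, f1_genotype(b, a)$combos)

  # a locus typed in only one parent is unpredictable, others evaluated
  f1 <- f1_genotype("s5-i;DPL1-N+", "s5-j")
  expect_equal(f1$unpredictable, "DPL1")
  expect_named(f1$combos, "s5")
})

test_that("the Sa rule requires a functional SaM heterozygote plus SaF+", {
  r <- evaluate_sa(c("SaM+", "SaM-"), c("SaF+", "SaF-"))
  expect_equal(r$verdict, "semi-sterile")
  expect_equal(r$viable_fraction, 0.5)

  # X alleles are nulls: the test-cross hybrid keeps full viability
  r <- evaluate_sa(c("SaM+X", "SaM-"), c("SaF+", "SaFX"))
  expect_equal(r$verdict, "compatible")
  expect_equal(r$viable_fraction, 1)

  # no heterozygote
  r <- evaluate_sa(c("SaM-", "SaM-"), c("SaF-", "SaF-"))
  expect_equal(r$verdict, "compatible")

  # heterozygote without any SaF+ is compatible
  r <- evaluate_sa(c("SaM+", "SaM-"), c("SaF-", "SaF-"))
  expect_equal(r$verdict, "compatible")

  # configurable effect size and the abstaining mode
  r <- evaluate_sa(c("SaM+", "SaM-"), c("SaF+", "SaF+"), effect_size = 0.4)
  expect_equal(r$viable_fraction, 0.6)
  r <- evaluate_sa(c("SaM+X", "SaM-"), c("SaF+", "SaFX"), x_mode = "unknown")
  expect_true(is.na(r$verdict))

  expect_error(evaluate_sa(c("SaM*", "SaM-"), c("SaF-", "SaF-")), "unknown")
})

test_that("the s5 rule reduces fertility only for the i/j heterodimer", {
  r <- evaluate_s5(c("s5-i", "s5-j"))
  expect_equal(r$verdict, "semi-sterile")
  expect_equal(r$fertility_reduction, 0.46)
  expect_equal(evaluate_s5(c("s5-n", "s5-j"))$fertility_reduction, 0)
  expect_equal(evaluate_s5(c("s5-n", "s5-i"))$fertility_reduction, 0)
  expect_equal(evaluate_s5(c("s5-i", "s5-i"))$fertility_reduction, 0)
  expect_error(evaluate_s5("s5-q"), "unknown")
})

test_that("the DPL rule equals gamete enumeration for all nine diploid classes", {
  dpl1_classes <- list(c("DPL1-N+", "DPL1-N+"), c("DPL1-N+", "DPL1-K-"),
                       c("DPL1-K-", "DPL1-K-"))
  dpl2_classes <- list(c("DPL2-K+", "DPL2-K+"), c("DPL2-K+", "DPL2-N-"),
                       c("DPL2-N-", "DPL2-N-"))
  for (g1 in dpl1_classes) {
    for (g2 in dpl2_classes) {
      expect_equal(evaluate_dpl(g1, g2)$viable_fraction,
                   oracle_dpl_viable(g1, g2),
                   info = paste(c(g1, g2), collapse = " "))
    }
  }
  # the three anchor cases
  expect_equal(evaluate_dpl(c("DPL1-K-", "DPL1-N+"),
                            c("DPL2-K+", "DPL2-N-"))$viable_fraction, 0.75)
  expect_equal(evaluate_dpl(c("DPL1-N+", "DPL1-N+"),
                            c("DPL2-N-", "DPL2-N-"))$viable_fraction, 1)
  expect_equal(evaluate_dpl(c("DPL1-K-", "DPL1-K-"),
                            c("DPL2-N-", "DPL2-N-"))$viable_fraction, 0)
})

test_that("cross prediction integrates the three systems multiplicatively", {
  sh <- "s5-n;DPL1-N+;DPL2-K+;SaM+X/SaFX"
  us_jap <- "s5-j;DPL1-N+;DPL2-K+;SaM-/SaF-"
  p <- predict_cross(sh, us_jap)
  expect_equal(p$combined_fertility, 1)
  expect_true(all(vapply(p$systems, `[[`, "", "verdict") == "compatible"))

  indica <- "s5-i;SaM+/SaF+;DPL1-K-;DPL2-K+"
  japonica <- "s5-j;SaM-/SaF-;DPL1-N+;DPL2-K+"
  p <- predict_cross(indica, japonica)
  expect_equal(p$systems$Sa$verdict, "semi-sterile")
  expect_equal(p$systems$s5$verdict, "semi-sterile")
  expect_equal(p$combined_fertility, 0.5 * 0.54)

  # self-cross of any homozygous parent is fully compatible
  for (g in c(sh, us_jap, indica)) {
    expect_equal(predict_cross(g, g)$combined_fertility, 1)
  }
})

test_that("cross prediction is symmetric and monotone under wide-compatibility substitution", {
  genos <- c("s5-i;SaM+/SaF+;DPL1-K-;DPL2-N-",
             "s5-j;SaM-/SaF-;DPL1-N+;DPL2-K+",
             "s5-n;SaM+X/SaFX;DPL1-N+;DPL2-K+",
             "s5-i;SaM+/SaF-;DPL1-K-;DPL2-K+")
  for (a in genos) {
    for (b in genos) {
      pa <- predict_cross(a, b)
      pb <- predict_cross(b, a)
      expect_equal(pa$combined_fertility, pb$combined_fertility)
    }
  }
  # replacing an allele by its null counterpart never decreases fertility
  swaps <- list(c("s5-i", "s5-n"), c("s5-j", "s5-n"),
                c("SaF+", "SaFX"), c("SaF-", "SaFX"))
  for (a in genos) {
    for (b in genos) {
      base <- predict_cross(a, b)$combined_fertility
      for (sw in swaps) {
        a2 <- sub(sw[1], sw[2], a, fixed = TRUE)
        expect_gte(predict_cross(a2, b)$combined_fertility, base)
      }
    }
  }
})

test_that("diploid parents are handled by averaging over gamete combinations", {
  # a wild SaM heterozygote crossed to an indica-type parent
  het <- list(SaM = c("SaM+", "SaM-"), SaF = c("SaF+", "SaF+"))
  hom <- list(SaM = "SaM-", SaF = "SaF-")
  p <- predict_cross(het, hom)
  # half the F1s are functional heterozygotes with SaF+ (0.5), half are
  # SaM-/SaM- (1.0)
  expect_equal(p$systems$Sa$viable_fraction, 0.75)
})

test_that("the population barrier matrix averages individual crosses", {
  counts <- rbind(
    data.frame(group = "SH", locus = "s5", allele = "s5-n", count = 6),
    data.frame(group = "SH", locus = "SaM", allele = "SaM+X", count = 6),
    data.frame(group = "SH", locus = "SaF", allele = "SaFX", count = 6),
    data.frame(group = "SH", locus = "DPL1", allele = "DPL1-N+", count = 6),
    data.frame(group = "SH", locus = "DPL2", allele = "DPL2-K+", count = 6),
    data.frame(group = "japonica", locus = "s5", allele = "s5-j", count = 4),
    data.frame(group = "japonica", locus = "SaM", allele = "SaM-", count = 4),
    data.frame(group = "japonica", locus = "SaF", allele = "SaF-", count = 4),
    data.frame(group = "japonica", locus = "DPL1", allele = "DPL1-N+", count = 4),
    data.frame(group = "japonica", locus = "DPL2", allele = "DPL2-K+", count = 4),
    data.frame(group = "BHA2", locus = "SaM", allele = "SaM+", count = 5),
    data.frame(group = "BHA2", locus = "SaF", allele = "SaF+", count = 5))
  p <- generate_panel_from_marginals(counts, seed = 13)
  M <- population_barrier_matrix(p$panel)

  # SH fixed for wide-compatibility alleles: no barrier to the crop
  expect_equal(M["SH", "japonica"], 1)
  # identical monomorphic groups
  expect_equal(M["SH", "SH"], 1)
  # BHA2 (SaM+/SaF+ fixed) x japonica (SaM-/SaF-): every cross triggers Sa
  expect_equal(M["BHA2", "japonica"], 0.5)
  expect_equal(M, t(M), ignore_attr = TRUE)
})

test_that("genotype strings parse and reject junk", {
  g <- parse_genotype("SaM+X/SaFX;s5-n;DPL1-N+;DPL2-K+")
  expect_named(g, c("SaM", "SaF", "s5", "DPL1", "DPL2"), ignore.order = TRUE)
  expect_equal(g$SaM, "SaM+X")
  d <- parse_genotype("SaM+X/SaM-//SaFX/SaF-")
  expect_setequal(d$SaM, c("SaM+X", "SaM-"))
  expect_setequal(d$SaF, c("SaFX", "SaF-"))
  expect_error(parse_genotype("s5-z"), "unrecognised")
})
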