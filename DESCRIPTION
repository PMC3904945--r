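Package: oryzacompat
Title: Hybrid-Incompatibility Allele Typing and Crop-Weed Compatibility
    Prediction in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the three cloned hybrid sterility systems of
    Asian rice (Sa, s5 and the DPL duplicate pair) in panels of cultivated,
    weedy and wild Oryza accessions. Classifies alleles at s5, DPL1, DPL2,
    SaM and SaF from aligned sequences and complementary-primer assays via
    their diagnostic polymorphisms (including the s5-n wide-compatibility
    deletion and the 8.6-kb SaFX deletion), builds population allele-type
    frequency and two-locus genotype-distribution tables, computes
    per-population diversity statistics (segregating sites, nucleotide
    diversity, Watterson's theta, Tajima's D), phases heterozygotes by
    haplotype subtraction, builds neighbor-joining haplotype genealogies
    under the Kimura two-parameter model with bootstrap support, predicts
    cross (in)compatibility and expected fertility for any genotype pair
    under the Bateson-Dobzhansky-Muller rules of the three systems, and
    summarises pollen viability and quantity measurements. A synthetic-data
    module generates aligned haplotype panels, genotype tables and pollen
    datasets with full ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
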