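Package: pedpanel
Title: Pedigree-Aware Sequencing Design and SNP Panel Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and quality-controlling whole-genome
    sequencing studies of large multi-generation pedigrees. Implements a
    greedy algorithm that ranks pedigree members by the number of their
    direct descendants to assign hierarchical sequencing coverage tiers, an
    in-silico read down-sampling harness that measures the effect of
    coverage allocation on trio Mendelian error rates, trio-constrained
    genotype refinement with consensus-haplotype construction from
    replicated nuclear units, staged variant QC filter cascades with
    per-filter accounting ledgers, identity-by-descent based sample QC and
    rule-based parentage assignment, LD thinning into association- and
    linkage-oriented marker panels, and genetic-map interpolation from STR
    anchors. A gene-dropping simulator produces pedigree-consistent phased
    genotypes with depth-dependent read counts so that every stage can be
    exercised end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
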