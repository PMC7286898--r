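Package: sveqtl
Title: Structural Variant and STR cis-eQTL Mapping with Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cis expression quantitative trait locus (eQTL) mapping toolkit for
    structural variants (SVs) and short tandem repeats (STRs). Converts
    caller-specific genotype fields (STR base-pair length differences, integer
    diploid copy numbers, allele-balance fractions, biallelic genotypes) to
    analysis-ready dosages with non-mode allele frequency filters; fits
    per-gene linear mixed models with a kinship random effect and
    likelihood-ratio tests; controls multiple testing with genotype
    permutations (beta-approximated or empirical) and Storey q-values;
    localises eQTL variants hierarchically against gene annotations; analyses
    variant length, gene constraint, promoter-capture Hi-C loop anchors, and
    linkage-disequilibrium tagging against a GWAS panel. Ships a truth-annotated
    synthetic cohort generator so the whole pipeline is testable without
    restricted-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
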