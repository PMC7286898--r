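# sveqtl

Cis-eQTL mapping for structural variants (SVs) and short tandem repeats
(STRs), with a truth-annotated synthetic cohort generator.

## The problem

SVs and STRs influence gene expression disproportionately relative to their
numbers, but analysing them takes machinery that SNV-centric eQTL tools do
not provide: callers emit heterogeneous genotype representations (STR
base-pair length differences, integer diploid copy numbers, allele-balance
fractions, plain biallelic genotypes), many variants are multiallelic so
minor allele frequency is ill-defined, and variant length spans orders of
magnitude. `sveqtl` is for statistical geneticists who want a tested,
self-contained pipeline for this setting.

The core model is a per-gene linear mixed model

```
y = C a + g b + u + e,   u ~ N(0, sg^2 K),   e ~ N(0, se^2 I)
```

with processed expression `y`, covariates `C`, variant dosage `g` on a 0-2
scale, and kinship `K` as the random-effect covariance. The model is fit by
maximum likelihood via one eigendecomposition of `K` per cohort; the
variance ratio is estimated once per gene under the null and reused across
cis variants. Each variant is tested with a 1-df likelihood-ratio test;
gene-level multiple testing uses permutations of the genotype block (beta
approximation or empirical rank of the permutation minima), and FDR across
genes uses Storey q-values. Around the scan sit: class-aware dosage
encoding with non-mode allele-frequency filters, a hierarchical 7-category
variant-gene localisation, variant-length enrichment and length/effect-size
models, gene-type and constraint (pLI/pRec/pNull) analyses, chromatin-loop
distal-anchor analysis, and LD tagging against a GWAS panel.

## Worked example

```r
library(sveqtl)

cfg <- simulation_config(n_samples = 120, n_genes = 30,
                         class_counts = c(SNV = 300, DEL = 40, DUP = 15,
                                          mCNV = 20, STR = 150, ALU = 20),
                         family_block_sizes = rep(4L, 10), seed = 11)
cohort  <- simulate_cohort(cfg)          # genotypes, kinship, TPM, loops, truth
dosages <- build_dosage_matrix(cohort$variants)
fit <- map_cis_eqtl(cohort$expression, dosages, cohort$genes$genes,
                    cohort$kinship, n_perm = 300, seed = 12)
summary(fit)
```

```
cis-eQTL summary: 8 eGenes / 30 tested genes (q < 0.05 , estimated pi0 = 1 )
  |lead beta| range: 0.27 - 0.727
       gene lead_variant  beta_lead   p_adjusted      q_value
G0001 G0001       V00122  0.7269288 8.066140e-20 2.419842e-18
G0007 G0007       V00375  0.6443448 1.347369e-08 2.021053e-07
G0013 G0013       V00154 -0.3931993 4.893649e-07 4.893649e-06
...
```

Eight of the simulation's nine planted eGenes are recovered at FDR < 5%; the
lead-variant effect sizes (`beta_lead`, standardized expression units per
dosage unit) track the planted effects in sign and relative magnitude (the
planted betas act on the standardized underlying genotype, so the scale
differs by the dosage standard deviation), and `pi0` is the estimated
proportion of null genes used by the Storey q-value step. Ground truth for
comparison is in `cohort$truth$planted_effects`.

Downstream analyses consume the fit and cohort directly, e.g.
`classify_pairs()` for the 7-category localisation, `length_enrichment()`
and `length_effect_models()` for the variant-length analyses,
`label_distal_pairs()` / `loop_distance_model()` for chromatin loops, and
`ld_tag_scan()` / `gwas_enrichment_tests()` for GWAS tagging. Cohorts
serialize to standard formats (VCF / GTF / BEDPE / TSV) with
`write_cohort()`.

See `vignettes/sveqtl-methods.Rmd` for the model details, generator design
and numerical choices.

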