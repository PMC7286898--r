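---
title: "Mapping SV and STR cis-eQTLs with sveqtl: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping SV and STR cis-eQTLs with sveqtl: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sveqtl)
```

## The problem

Structural variants (SVs) and short tandem repeats (STRs) are major sources
of human genetic variation but are harder to genotype and analyse than SNVs:
they are often multiallelic, their callers emit heterogeneous genotype
representations, and their length spans orders of magnitude. `sveqtl`
implements a complete cis expression quantitative trait locus (eQTL)
pipeline specialised for these variant classes: class-aware dosage encoding,
a linear mixed model (LMM) association scan with permutation-based
gene-level multiple-testing control, hierarchical genomic localisation of
eQTL variants, chromatin-loop distal-anchor analysis, gene-constraint
analysis, and linkage-disequilibrium (LD) tagging against a GWAS panel.

Because the cohorts such studies are run on are restricted-access, the
package ships a truth-annotated synthetic cohort generator
(`simulate_cohort()`) that reproduces the *statistical structure* of such a
study — a few hundred related donors, twelve variant classes with
caller-specific raw encodings, planted cis effects, latent expression
confounders, promoter-anchored chromatin loops and tunable-LD tag SNVs — so
every stage of the pipeline can be validated against a known ground truth.

## Genotype encoding

Raw caller fields are converted to continuous dosages on a 0–2 scale
(`build_dosage_matrix()`):

* **STRs** (`str_gb`): the per-sample genotype is a pair of base-pair length
  differences from the reference; the raw dosage is their sum.
* **Copy-number classes** (`copy_number`: duplications, multiallelic CNVs):
  the integer diploid copy number.
* **Allele-balance classes** (`allele_balance`: deletions, inversions,
  break-ends, reference MEIs): a fraction in [0, 1] quantifying read
  evidence for the variant allele.
* **Biallelic genotypes** (`biallelic_gt`: non-reference MEIs, SNVs,
  indels): 0/0, 0/1, 1/1 become 0, 1, 2.

All encodings except `biallelic_gt` are rank-normalised: non-missing values
are replaced by average-tie ranks mapped affinely by
$(r - 1)/(n - 1) \times 2$, so rank 1 maps to 0 and rank $n$ to 2. The exact
rank recipe is a design choice (an affine rank map rather than an
inverse-normal transform): it is monotone, bounded, and stable under ties.
Missing entries are imputed *after* scaling with the mean dosage among
non-missing samples, so imputed values live on the analysis scale.

Variant inclusion uses the **non-mode allele frequency** (NMAF) — the
fraction of calls differing from the modal call, the multiallelic analogue
of minor allele frequency. For allele-resolved encodings (STR length
differences, biallelic genotypes) it is counted at the allele level; for
copy-number and allele-balance encodings at the sample-call level, with
mode ties broken toward the reference-like value (length diff 0, CN 2,
AB 0). Thresholds: NMAF ≥ 0.05 (SVs/STRs), MAF ≥ 0.05 (SNVs/indels), and a
99% pre-imputation call rate for STRs. Redundant variant calls (shared
`cluster_id`) are retained, with the cluster id available for unique-variant
counting.

## The association model

For each gene, expression is filtered (expressed in > 20% of samples, mean
TPM > 0.5 among expressing samples), log-transformed as
$\log_2(\mathrm{TPM} + 1)$ (the transform base is a design choice) and
standardised. The null model per gene is

$$ y = C\alpha + u + e, \qquad u \sim N(0, \sigma_g^2 K), \quad
   e \sim N(0, \sigma_e^2 I), $$

with covariates $C$ (supplied externally, or expression principal
components as a stand-in for latent-factor covariates — 10 by default) and
kinship $K$ capturing population and family structure. One
eigendecomposition of $K$ rotates the model to independent observations;
the variance ratio $\delta = \sigma_e^2/\sigma_g^2$ is estimated once per
gene under the null by maximum likelihood (profiled over $\log\delta$) and
reused for every cis variant — standard fast-LMM practice. Each variant in
the cis window (gene body ± 1 Mb, interval intersection) is then tested as
a fixed effect $g\beta$ with a 1-df likelihood-ratio test,
$\mathrm{LRT} = n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ clipped at zero.

With $K = cI$ the model collapses to OLS; the test suite verifies agreement
with an independent OLS likelihood-ratio oracle to $10^{-6}$.

### Multiple testing

Gene-level adjustment permutes the sample rows of the cis genotype block
jointly (one permutation per replicate for all cis variants, preserving
local LD) while expression, covariates and kinship stay fixed, and records
the minimum nominal p per permutation (1000 by default). Two summaries are
available: the default fits a beta distribution to the permutation minima by
maximum likelihood and evaluates its CDF at the observed minimum; an
`empirical` mode uses the rank formula $(1 + \#\{p^{perm}_{min} \le
p_{obs}\})/(n_{perm} + 1)$. The two agree to Spearman correlation > 0.99 on
simulated genes; the beta summary resolves p-values below the $1/(n_{perm}
+ 1)$ granularity. The adjusted p is floored at the observed minimum nominal
p. Across genes, Storey q-values control the FDR; eGenes are genes with
q < 0.05, and the lead eVariant is the cis variant with the smallest
nominal p (ties broken by distance to the TSS, then variant id).

The Storey $\pi_0$ estimate uses the standard cubic-polynomial smoother over
$\lambda \in \{0.05, \dots, 0.95\}$ evaluated at the largest $\lambda$. On
lists shorter than 100 p-values the smoother is very unstable (a handful of
small p-values can drive $\hat\pi_0$ toward 0), so the implementation uses
$\pi_0 = 1$ there, making the q-values coincide with Benjamini–Hochberg —
the conservative choice.

## Localisation and enrichment analyses

Each variant–gene pair receives exactly one of seven hierarchical
categories — exonic eGene > promoter eGene > intronic eGene > exonic other
> promoter other > intronic other > intergenic — where overlap means
sharing at least one base pair, and an intron is the gene body minus exons
minus promoter. The promoter is a strand-aware window of 2 kb upstream to
500 bp downstream of the TSS (the interval is configurable; no canonical
definition exists).

Variant-length analyses use Fisher's exact test comparing eVariant
proportions above vs below length thresholds (BH-adjusted within class),
and a regression of the absolute lead effect size on $\log_{10}$ length
with NMAF and TSS distance as covariates. Both a linear model (t-test,
default) and a logistic variant are provided: the two descriptions coexist
in the field's practice for this analysis, and the linear form is the more
natural one for a continuous |effect size| response. Odds ratios are sample
cross-product ratios with a Haldane–Anscombe 0.5 correction on zero cells,
keeping them finite and testable.

Chromatin-loop analysis labels distal variant–gene pairs by four criteria:
closer to the distal than the promoter anchor (midpoint distances — an
unambiguous choice for interval variants), at least 50 kb from the promoter
(a gene-body variant of the criterion is available as a flag), at most
200 kb from the distal anchor, and no exon overlap with the tested gene
(toggleable; included by default). When a gene has several loops the
nearest qualifying loop is used. Variants within 10 kb of an anchor count
as intersecting it.

LD tagging computes squared Pearson correlation between dosage vectors —
well-defined for multiallelic and continuous encodings — against panel SNVs
within a closed 50 kb window of the variant boundaries; a variant is tagged
when the best in-panel r² exceeds 0.8, and is linked to a trait when a
trait-significant SNV (p < 5e-8) is itself in strong LD with it.

## The synthetic cohort

`simulation_config()` defaults encode the emulated study conditions:
398 donors (with 25 family blocks of 4; the kinship is block-diagonal
family relatedness plus identity, normalised to unit mean diagonal — the
real cohort's kinship spectrum is not public, so this is a modelling
choice), twelve variant classes in roughly the proportions of a tested
common-variant census, class-specific log-uniform length bounds (STR
2–100 bp; DEL/DUP/mCNV/INV 50 bp–1 Mb; MEI classes near their biological
insert sizes), 30% of genes carrying one planted cis effect with
standardised $|\beta|$ uniform in 0.5–1.5 across exonic, promoter, proximal
and loop-distal mechanisms (exonic mCNV effects positive, reflecting
dosage gain), five dense latent confounders, a polygenic term explaining
20% of residual latent variance, and 0.2% genotype missingness (deep-WGS
scale; at much higher rates the 99% STR call-rate filter would remove the
class wholesale). Planted effects are drawn only from variants that pass
the inclusion filters, so every planted effect is recoverable in principle.
Latent expression maps to TPM by the fixed monotone transform
$\mathrm{TPM} = \max(e^{\mathrm{latent} + b_g} - 0.25,\, 0)$ with
gene-specific baselines, which the log/standardise step inverts on the
expressed range.

The generator reproduces the *structure* the analysis assumes, not real
data: a single chromosome, no LD between distinct variants (except
planted tag SNVs), no realistic allele-frequency spectrum, no read-level
error model. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not performance on
real cohorts.

Desk-scale problem sizes are used throughout the tests (500 genes for null
calibration at 100 samples and 20 cis variants per gene; 20 replicate
cohorts of 200 samples and 40 genes for FDR/power; 10,000 samples for
frequency-convergence checks) — chosen so the whole suite runs on a single
CPU in minutes while keeping Monte-Carlo error well below the tested
margins.

## Numerical choices and degenerate inputs

* Variance-ratio optimisation is over $\log\delta \in [-12, 12]$; kinship
  eigenvalues are clipped at zero (PSD is enforced to $-10^{-8}$).
* Constant genotype vectors cannot be rank-scaled and are rejected; they
  cannot pass the NMAF filter anyway. Constant cis variants inside a scan
  are flagged per variant and the scan continues.
* The beta fit to permutation minima falls back to the empirical rank
  formula when maximum likelihood fails; permutation counts below 100 draw
  a warning.
* Fisher's two-sided p is the conventional probability-mass definition
  (sum of tables with point probability ≤ observed). The Mann–Whitney U
  test enumerates all group assignments exactly for combined n ≤ 12 (exact
  under ties), and otherwise uses the tie-corrected normal approximation.
* Logistic fits flag perfect separation and abstain from p-values;
  fractional responses (allele-balance-style or probability responses such
  as pLI) use quasi-binomial likelihood with t-tests.

## A worked run

```{r example, eval = FALSE}
cfg <- simulation_config(n_samples = 120, n_genes = 30,
                         class_counts = c(SNV = 300, DEL = 40, DUP = 15,
                                          mCNV = 20, STR = 150, ALU = 20),
                         family_block_sizes = rep(4L, 10), seed = 11)
cohort <- simulate_cohort(cfg)
dosages <- build_dosage_matrix(cohort$variants)
fit <- map_cis_eqtl(cohort$expression, dosages, cohort$genes$genes,
                    cohort$kinship, n_perm = 300, seed = 12)
summary(fit)
```

## Known limitations

* No conditional/secondary-signal mapping, trans-eQTLs, fine-mapping or
  colocalisation.
* Latent-factor covariate estimation is not implemented; expression PCs or
  user-supplied covariates stand in.
* LD r² is dosage-based, not haplotype-phased.
* The generator's single-chromosome, LD-free genome makes lead-variant
  identification easier than in real data, where LD can displace the lead
  onto a tagging variant.
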