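# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher p by explicit hypergeometric enumeration: sum of the
# probabilities of all tables (with the observed margins) whose point
# probability is at most the observed one.
fisher_two_sided_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# OLS likelihood-ratio p-value for one variant (chi-square 1 df), the
# independent oracle for the mixed model with identity kinship.
ols_lrt_oracle <- function(y, C, g) {
  if (is.null(C) || NCOL(C) == 0) {
    f0 <- stats::lm(y ~ 1)
    f1 <- stats::lm(y ~ g)
  } else {
    f0 <- stats::lm(y ~ C)
    f1 <- stats::lm(y ~ C + g)
  }
  lrt <- 2 * as.numeric(stats::logLik(f1) - stats::logLik(f0))
  stats::pchisq(lrt, df = 1, lower.tail = FALSE)
}

# One-variant variant_records fixture.
one_variant <- function(raw, class = "STR",
                        encoding = c(STR = "str_gb", DEL = "allele_balance",
                                     mCNV = "copy_number",
                                     SNV = "biallelic_gt")[[class]],
                        start = 1000, length = 10) {
  samples <- sprintf("S%03d", seq_along(raw))
  info <- data.frame(id = "v1", variant_class = class, chrom = "chr1",
                     start = start, end = start + length, length = length,
                     encoding = encoding, stringsAsFactors = FALSE)
  m <- matrix(raw, nrow = 1, dimnames = list("v1", samples))
  variant_records(info, m)
}

# Random single-variant raw field vector of a given encoding.
random_raw <- function(encoding, n) {
  switch(encoding,
    str_gb = {
      alleles <- sample(c(0, 2, -2, 4, -1), 2 * n, replace = TRUE)
      paste0(alleles[1:n], "|", alleles[(n + 1):(2 * n)])
    },
    copy_number = as.character(sample(0:5, n, replace = TRUE)),
    allele_balance = formatC(round(stats::runif(n), 3), format = "f", digits = 3),
    biallelic_gt = sample(c("0/0", "0/1", "1/1"), n, replace = TRUE))
}

# Minimal gene_models fixture: one gene with one exon, plus optionally a
# second ("other") gene.
tiny_gene_models <- function(with_other = TRUE) {
  genes <- data.frame(
    id = c("gA", if (with_other) "gB"),
    chrom = "chr1", strand = "+",
    start = c(100000, if (with_other) 300000),
    end = c(120000, if (with_other) 330000),
    tss = c(100000, if (with_other) 300000),
    gene_type = "protein_coding", stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", if (with_other) "gB"),
    start = c(100000, 110000, if (with_other) 300000),
    end = c(101000, 111000, if (with_other) 301000),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

# Small cohort configuration used by several integration tests.
small_config <- function(seed = 1, ...) {
  simulation_config(
    n_samples = 80, n_genes = 15,
    class_counts = c(SNV = 120, indel = 30, DEL = 20, DUP = 10, mCNV = 10,
                     STR = 60, ALU = 10),
    family_block_sizes = rep(4L, 5), seed = seed, ...)
}
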