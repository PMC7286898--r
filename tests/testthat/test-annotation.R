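test_that("promoter interval is strand aware and contains the TSS", {
  p <- promoter_interval(10000, "+")
  expect_equal(p, c(8000, 10500))
  m <- promoter_interval(10000, "-")
  expect_equal(m, c(9501, 12001))
  for (s in c("+", "-")) {
    pr <- promoter_interval(5000, s)
    expect_true(pr[1] <= 5000 && 5000 < pr[2])
  }
})

test_that("hierarchical classification follows the 7-category precedence", {
  models <- tiny_gene_models()
  # gA: body [100000,120000), exons [100000,101000)+[110000,111000),
  #     promoter [98000,100500); gB: body [300000,330000)
  v <- function(s, e) list(chrom = "chr1", start = s, end = e)
  expect_equal(classify_variant_gene(v(100500, 100600), "gA", models),
               "exonic_egene")
  expect_equal(classify_variant_gene(v(98500, 98600), "gA", models),
               "promoter_egene")
  expect_equal(classify_variant_gene(v(105000, 105100), "gA", models),
               "intronic_egene")
  expect_equal(classify_variant_gene(v(300500, 300600), "gA", models),
               "exonic_other")
  expect_equal(classify_variant_gene(v(299000, 299100), "gA", models),
               "promoter_other")
  expect_equal(classify_variant_gene(v(310000, 310100), "gA", models),
               "intronic_other")
  expect_equal(classify_variant_gene(v(200000, 200100), "gA", models),
               "intergenic")
  # precedence: spans both an eGene exon and the other gene's exon
  expect_equal(classify_variant_gene(v(100500, 300500), "gA", models),
               "exonic_egene")
  # eGene intron beats other-gene exon (category 3 before 4): overlaps the
  # second gA intron [111000, 120000) and gB's exon, but no gA exon
  expect_equal(classify_variant_gene(v(115000, 300500), "gA", models),
               "intronic_egene")
})

test_that("adding lower-precedence overlaps never changes the category", {
  models <- tiny_gene_models()
  v1 <- list(chrom = "chr1", start = 100500, end = 100600)  # exonic eGene
  base <- classify_variant_gene(v1, "gA", models)
  v2 <- list(chrom = "chr1", start = 100500, end = 310100)  # + everything else
  expect_equal(classify_variant_gene(v2, "gA", models), base)
})

test_that("classification is exhaustive and mutually exclusive", {
  set.seed(71)
  models <- tiny_gene_models()
  cats <- vapply(1:100, function(i) {
    s <- sample(90000:340000, 1)
    classify_variant_gene(list(chrom = "chr1", start = s,
                               end = s + sample(c(1, 100, 5000), 1)),
                          "gA", models)
  }, character(1))
  expect_true(all(cats %in% c("exonic_egene", "promoter_egene",
                              "intronic_egene", "exonic_other",
                              "promoter_other", "intronic_other",
                              "intergenic")))
})

test_that("distances to TSS and gene body follow gap arithmetic", {
  d <- distance_to_gene(list(start = 100, end = 200),
                        list(start = 400, end = 900, tss = 150))
  expect_equal(d$to_tss, 0)
  expect_equal(d$to_body, 200)
  d2 <- distance_to_gene(list(start = 100, end = 200),
                         list(start = 400, end = 900, tss = 500))
  expect_equal(d2$to_tss, 300)
})

test_that("distances are invariant under coordinate translation", {
  set.seed(72)
  for (i in 1:20) {
    s <- sample(1e5, 1); e <- s + sample(1000, 1)
    gs <- sample(1e5, 1); ge <- gs + sample(5000, 1)
    off <- sample(1e6, 1)
    d1 <- distance_to_gene(list(start = s, end = e),
                           list(start = gs, end = ge, tss = gs))
    d2 <- distance_to_gene(list(start = s + off, end = e + off),
                           list(start = gs + off, end = ge + off,
                                tss = gs + off))
    expect_equal(d1, d2)
  }
})

test_that("length enrichment reproduces the 2x2 odds-ratio identity", {
  variants <- data.frame(
    variant_class = "DEL",
    length = c(rep(1000, 10), rep(10, 10)),
    is_evariant = c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8)),
    is_lead = FALSE, stringsAsFactors = FALSE)
  r <- length_enrichment(variants, thresholds = 100, classes = "DEL")
  ev <- r[r$outcome == "is_evariant", ]
  expect_equal(ev$odds_ratio, (8 * 8) / (2 * 2))
  expect_equal(ev$p, fisher_two_sided_oracle(matrix(c(8, 2, 2, 8), 2,
                                                    byrow = TRUE)),
               tolerance = 1e-10)
  # identical proportions on both sides -> OR = 1
  variants$is_evariant <- rep(c(TRUE, FALSE), 10)
  r2 <- length_enrichment(variants, thresholds = 100, classes = "DEL")
  expect_equal(r2$odds_ratio[r2$outcome == "is_evariant"], 1)
})

test_that("length enrichment OR matches the count identity on random fixtures", {
  set.seed(73)
  for (i in 1:30) {
    v <- data.frame(variant_class = "STR",
                    length = sample(c(5, 500), 40, replace = TRUE),
                    is_evariant = runif(40) < 0.4, is_lead = FALSE,
                    stringsAsFactors = FALSE)
    r <- length_enrichment(v, thresholds = 50, classes = "STR")
    row <- r[r$outcome == "is_evariant", ]
    if (!row$testable) next
    a <- row$a; b <- row$b; cc <- row$c; d <- row$d
    or_oracle <- if (any(c(a, b, cc, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else (a * d) / (b * cc)
    expect_equal(row$odds_ratio, or_oracle)
  }
})

test_that("empty strata are flagged untestable", {
  v <- data.frame(variant_class = "DUP", length = rep(10, 5),
                  is_evariant = TRUE, is_lead = FALSE,
                  stringsAsFactors = FALSE)
  r <- length_enrichment(v, thresholds = 100, classes = "DUP")
  expect_false(any(r$testable))
  expect_true(all(is.na(r$p)))
})

test_that("length_effect_model recovers a planted slope", {
  set.seed(74)
  n <- 500
  len <- round(exp(runif(n, log(50), log(1e6))))
  eq <- data.frame(
    abs_beta = 0.1 + 0.3 * log10(len) + rnorm(n, 0, 0.1),
    length = len, nmaf = runif(n, 0.05, 0.5),
    distance_to_tss = runif(n, 0, 1e6))
  m <- length_effect_model(eq)
  expect_gte(m$slope, 0.25); expect_lte(m$slope, 0.35)
  expect_lt(m$p, 1e-10)
  # degenerate: all lengths equal -> collinear with the intercept
  eq$length <- 100
  expect_error(length_effect_model(eq), "rank deficient|collinear")
})

test_that("length_effect_model is null-calibrated under permutation", {
  set.seed(75)
  ps <- replicate(100, {
    n <- 120
    len <- round(exp(runif(n, log(50), log(1e5))))
    eq <- data.frame(abs_beta = sample(0.1 + 0.3 * log10(len) + rnorm(n, 0, 0.2)),
                     length = len, nmaf = runif(n, 0.05, 0.5),
                     distance_to_tss = runif(n, 0, 1e6))
    length_effect_model(eq)$p
  })
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("egene property tests compute the documented odds ratios", {
  set.seed(76)
  egenes <- data.frame(
    gene = sprintf("e%02d", 1:10), lead_class = "DEL", abs_beta = runif(10),
    gene_type = "protein_coding",
    pli = c(0.95, runif(9, 0, 0.5)), prec = 0.5, pnull = 0.2,
    mean_log_tpm = rnorm(10), stringsAsFactors = FALSE)
  non <- data.frame(gene = sprintf("n%02d", 1:10),
                    gene_type = "protein_coding",
                    pli = c(rep(0.95, 5), rep(0.1, 5)), prec = 0.5,
                    pnull = 0.2, stringsAsFactors = FALSE)
  r <- egene_property_tests(egenes, non)
  pli_row <- r$constraint[r$constraint$score == "pli" &
                            r$constraint$class == "DEL", ]
  expect_equal(pli_row$odds_ratio, (1 * 5) / (9 * 5))
  # identical composition -> OR 1 for the gene-type test
  expect_true(all(r$gene_type$odds_ratio == 1 | is.na(r$gene_type$odds_ratio)))
})

test_that("a planted negative pLI-effect relationship is recovered", {
  set.seed(77)
  n <- 400
  ab <- runif(n, 0.2, 2)
  pli <- plogis(1.5 - 2 * ab + rnorm(n, 0, 0.5))
  egenes <- data.frame(gene = sprintf("e%03d", 1:n), lead_class = "STR",
                       abs_beta = ab, gene_type = "protein_coding",
                       pli = pli, prec = 0.5, pnull = 0.2,
                       mean_log_tpm = rnorm(n), stringsAsFactors = FALSE)
  non <- data.frame(gene = "n1", gene_type = "protein_coding", pli = 0.5,
                    prec = 0.5, pnull = 0.2, stringsAsFactors = FALSE)
  r <- egene_property_tests(egenes, non)
  expect_lt(r$pli_model$estimate, 0)
  expect_lt(r$pli_model$p, 0.01)
})

test_that("GTF round trip preserves gene models", {
  co <- simulate_cohort(small_config(seed = 21))
  path <- tempfile(fileext = ".gtf")
  write_gene_models_gtf(co$genes, path)
  back <- read_gene_models(path)
  o <- match(co$genes$genes$id, back$genes$id)
  expect_equal(back$genes$start[o], co$genes$genes$start)
  expect_equal(back$genes$end[o], co$genes$genes$end)
  expect_equal(back$genes$tss[o], co$genes$genes$tss)
  expect_equal(back$genes$gene_type[o], co$genes$genes$gene_type)
  expect_equal(nrow(back$exons), nrow(co$genes$exons))
  unlink(path)
})
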