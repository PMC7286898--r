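test_that("simulation is deterministic given the seed, including files", {
  cfg <- small_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants$raw, b$variants$raw)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth$planted_effects, b$truth$planted_effects)
  expect_identical(a$loops, b$loops)
  da <- tempfile(); db <- tempfile()
  write_cohort(a, da); write_cohort(b, db)
  for (f in list.files(da)) {
    expect_identical(readLines(file.path(da, f)), readLines(file.path(db, f)),
                     info = f)
  }
  unlink(c(da, db), recursive = TRUE)
})

test_that("fraction_egenes = 0 plants nothing and loop_density = 0 gives no loops", {
  co <- simulate_cohort(small_config(seed = 2, fraction_egenes = 0,
                                     loop_density = 0))
  expect_equal(nrow(co$truth$planted_effects), 0)
  expect_equal(nrow(co$loops), 0)
})

test_that("every mCNV realizes at least 3 distinct copy-number states", {
  cfg <- simulation_config(n_samples = 100, n_genes = 5,
                           class_counts = c(mCNV = 5, SNV = 10),
                           family_block_sizes = integer(0), seed = 3)
  co <- simulate_cohort(cfg)
  mcnv <- co$variants$info$id[co$variants$info$variant_class == "mCNV"]
  expect_length(mcnv, 5)
  for (v in mcnv) {
    raw <- co$variants$raw[v, ]
    cn <- suppressWarnings(as.numeric(raw[raw != "."]))
    expect_gte(length(unique(cn)), 3)
  }
})

test_that("missing_rate = 0 yields no missing genotype entries", {
  co <- simulate_cohort(small_config(seed = 4, missing_rate = 0))
  expect_false(any(co$variants$raw == "."))
})

test_that("realized allele frequencies track the binomial draw at n = 10,000", {
  cfg <- simulation_config(n_samples = 10000, n_genes = 1,
                           class_counts = c(ALU = 25), missing_rate = 0,
                           family_block_sizes = integer(0), seed = 5)
  rec <- simulate_genotypes(cfg, rng_state = 5)
  af <- attr(rec, "alt_af")
  for (i in seq_len(nrow(rec$info))) {
    g <- raw_to_dosage(rec$raw[i, ], "biallelic_gt")
    expect_lt(abs(mean(g) / 2 - af[i]), 0.02)
  }
})

test_that("invalid configuration fields are named in the error", {
  expect_error(simulation_config(fraction_egenes = 1.5), "fraction_egenes")
  expect_error(simulation_config(polygenic_variance = -0.1),
               "polygenic_variance")
  expect_error(simulation_config(n_samples = 4,
                                 family_block_sizes = c(4L, 4L)),
               "family block")
  expect_error(simulation_config(class_counts = c(BAD = 10)), "class_counts")
  expect_error(simulation_config(length_bounds = list(SNV = c(2, 1))),
               "length_bounds")
})

test_that("kinship is PSD with unit mean diagonal and family blocks", {
  cfg <- small_config(seed = 6)
  K <- simulate_kinship(cfg, rng_state = 6)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(mean(diag(K)), 1)
  expect_gt(K[1, 2], 0)  # first family block
  expect_equal(K[1, cfg$n_samples], 0)
})

test_that("a single strong planted effect dominates the latent expression", {
  cfg <- simulation_config(n_samples = 150, n_genes = 4,
    class_counts = c(SNV = 30, DEL = 10), fraction_egenes = 0.25,
    base_effect = 1, beta_spread = 0, n_confounders = 0,
    polygenic_variance = 0, noise_sd = 0.001,
    family_block_sizes = integer(0), missing_rate = 0, seed = 8)
  co <- simulate_cohort(cfg)
  tr <- co$truth$planted_effects
  expect_equal(nrow(tr), 1)
  d <- attr(co$variants, "underlying")[tr$variant, ]
  expect_gt(abs(cor(co$truth$latent[tr$gene, ], d)), 0.999)
})

test_that("with no signal sources, genes are uncorrelated noise", {
  cfg <- simulation_config(n_samples = 100, n_genes = 200,
    class_counts = c(SNV = 20), fraction_egenes = 0, n_confounders = 0,
    polygenic_variance = 0, noise_sd = 1, family_block_sizes = integer(0),
    seed = 9)
  ex <- simulate_expression(simulate_genotypes(cfg, 9),
                            data.frame(gene = character(),
                                       variant = character(),
                                       beta = numeric()),
                            simulate_kinship(cfg, 9), cfg,
                            simulate_gene_models(cfg, 9), rng_state = 10)
  cc <- cor(t(ex$latent))
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.02)
})

test_that("pure polygenic expression has covariance proportional to kinship", {
  cfg <- simulation_config(n_samples = 60, n_genes = 400,
    class_counts = c(SNV = 20), fraction_egenes = 0, n_confounders = 0,
    polygenic_variance = 1, noise_sd = 0, family_block_sizes = rep(6L, 8),
    seed = 10)
  ex <- simulate_expression(simulate_genotypes(cfg, 10),
                            data.frame(gene = character(),
                                       variant = character(),
                                       beta = numeric()),
                            simulate_kinship(cfg, 10), cfg,
                            simulate_gene_models(cfg, 10), rng_state = 11)
  K <- simulate_kinship(cfg, 10)
  S <- cov(ex$latent)  # sample covariance across genes
  off <- upper.tri(K)
  expect_gt(cor(S[off], K[off]), 0.9)
})

test_that("loops anchor at promoters and planted distal pairs pass the filter", {
  co <- simulate_cohort(small_config(seed = 12, loop_density = 2))
  pr <- co$genes$promoters
  for (i in seq_len(nrow(co$loops))) {
    l <- co$loops[i, ]
    p <- pr[pr$gene_id == l$gene, ]
    expect_true(l$p_start < p$end && p$start < l$p_end)
    # anchors disjoint
    expect_true(l$d_start >= l$p_end || l$d_end <= l$p_start)
  }
  lp <- co$truth$looped_pairs
  for (i in seq_len(nrow(lp))) {
    v <- co$variants$info[co$variants$info$id == lp$variant[i], ]
    lab <- distal_pair_filter(v, lp$gene[i], co$loops, co$genes)
    expect_true(lab$is_distal_pair, info = lp$variant[i])
  }
})

test_that("gwas tags hit their target r2 and trait links obey the threshold", {
  cfg <- simulation_config(n_samples = 10000, n_genes = 1,
    class_counts = c(DEL = 15, STR = 15), tag_fraction = 1,
    tag_r2_bounds = c(0.5, 0.5), missing_rate = 0,
    family_block_sizes = integer(0), seed = 13)
  rec <- simulate_genotypes(cfg, rng_state = 13)
  panel <- simulate_gwas_panel(rec, cfg, rng_state = 14)
  und <- attr(rec, "underlying")
  for (i in seq_len(nrow(panel$snvs))) {
    r2 <- ld_r2(und[panel$snvs$source_variant[i], ], panel$dosages[i, ])
    expect_gte(r2, 0.45); expect_lte(r2, 0.55)
  }
  # exact-tag case: zero noise
  cfg1 <- simulation_config(n_samples = 200, n_genes = 1,
    class_counts = c(DEL = 5), tag_fraction = 1, tag_r2_bounds = c(1, 1),
    missing_rate = 0, family_block_sizes = integer(0), seed = 15)
  rec1 <- simulate_genotypes(cfg1, rng_state = 15)
  p1 <- simulate_gwas_panel(rec1, cfg1, rng_state = 16)
  u1 <- attr(rec1, "underlying")
  for (i in seq_len(nrow(p1$snvs))) {
    expect_equal(ld_r2(u1[p1$snvs$source_variant[i], ], p1$dosages[i, ]), 1)
  }
  # every recorded trait link is genome-wide significant; no uniform p leaks in
  links <- merge(panel$trait_links, panel$traits)
  expect_true(all(links$p < 5e-8))
})

test_that("planted effects are recoverable in principle", {
  co <- simulate_cohort(small_config(seed = 17))
  dm <- build_dosage_matrix(co$variants)
  kept_genes <- prepare_expression(co$expression)$kept
  tr <- co$truth$planted_effects
  expect_true(all(tr$variant %in% dm$variants$id))
  expect_true(all(tr$gene %in% kept_genes))
  # planted pairs lie inside the cis window
  for (i in seq_len(nrow(tr))) {
    g <- co$genes$genes[co$genes$genes$id == tr$gene[i], ]
    expect_true(tr$variant[i] %in% cis_pairs(g, dm$variants))
  }
})
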