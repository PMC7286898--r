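make_loop <- function(gene = "gA", p = c(98000, 103000), d = c(400000, 410000)) {
  data.frame(loop_id = "L1", gene = gene, chrom = "chr1",
             p_start = p[1], p_end = p[2], d_start = d[1], d_end = d[2],
             stringsAsFactors = FALSE)
}

test_that("anchor_intersect uses a 10 kb slop with closed boundary", {
  a <- c(50000, 60000)
  v <- function(s, e) list(start = s, end = e)
  expect_true(anchor_intersect(v(40001, 40002), a[1], a[2]))   # gap 9,998
  expect_true(anchor_intersect(v(40000, 40001), a[1], a[2]))   # gap 9,999... within
  expect_false(anchor_intersect(v(29998, 29999), a[1], a[2]))  # gap 20,001
  expect_false(anchor_intersect(v(39998, 39999), a[1], a[2]))  # gap 10,001
  expect_true(anchor_intersect(v(55000, 55100), a[1], a[2]))   # overlap
})

test_that("distal_pair_filter checks all four criteria", {
  models <- tiny_gene_models(with_other = FALSE)
  loops <- make_loop()
  v <- function(s, len = 100) {
    list(id = "v", chrom = "chr1", start = s, end = s + len)
  }
  # 290 kb from the promoter, 10 kb short of the distal anchor
  ok <- distal_pair_filter(v(390000), "gA", loops, models)
  expect_true(ok$is_distal_pair)
  # closer to the distal anchor but < 50 kb from the promoter
  loops_near <- make_loop(d = c(180000, 190000))
  near_prom <- distal_pair_filter(v(150000), "gA", loops_near, models)
  expect_false(near_prom$is_distal_pair)
  expect_equal(near_prom$reason, "promoter_gap")
  # 250 kb beyond the distal anchor
  far <- distal_pair_filter(v(660000), "gA", loops, models)
  expect_false(far$is_distal_pair)
  expect_equal(far$reason, "anchor_gap")
  # closer to the promoter anchor than the distal anchor
  closer_p <- distal_pair_filter(v(160000), "gA", loops, models)
  expect_false(closer_p$is_distal_pair)
  expect_equal(closer_p$reason, "closer_to_promoter_anchor")
  # exon overlap with the tested gene, all other criteria satisfied
  big <- gene_models(
    data.frame(id = "gA", chrom = "chr1", strand = "+", start = 100000,
               end = 300000, tss = 100000, gene_type = "protein_coding",
               stringsAsFactors = FALSE),
    data.frame(gene_id = "gA", start = 200000, end = 201000,
               stringsAsFactors = FALSE))
  loops2 <- make_loop(d = c(199000, 202000))
  ex <- distal_pair_filter(list(id = "v", chrom = "chr1", start = 200500,
                                end = 200600), "gA", loops2, big)
  expect_false(ex$is_distal_pair)
  expect_equal(ex$reason, "exon_overlap")
  exoff <- distal_pair_filter(list(id = "v", chrom = "chr1", start = 200500,
                                   end = 200600), "gA", loops2, big,
                              exclude_exon_overlap = FALSE)
  expect_true(exoff$is_distal_pair)
  # gene without loops
  nl <- distal_pair_filter(v(390000), "gZ", loops, models)
  expect_false(nl$is_distal_pair)
  expect_equal(nl$reason, "no_loop")
})

test_that("inside_loop reflects midpoint position between anchors", {
  models <- tiny_gene_models(with_other = FALSE)
  loops <- make_loop()
  inside <- distal_pair_filter(list(id = "v", chrom = "chr1",
                                    start = 350000, end = 350100),
                               "gA", loops, models)
  expect_true(inside$inside_loop)
  outside <- distal_pair_filter(list(id = "v", chrom = "chr1",
                                     start = 450000, end = 450100),
                                "gA", loops, models)
  expect_false(outside$inside_loop)
})

test_that("filter is monotone in its thresholds", {
  set.seed(81)
  models <- tiny_gene_models(with_other = FALSE)
  loops <- make_loop()
  starts <- sample(100000:700000, 200)
  lab_wide <- vapply(starts, function(s) {
    distal_pair_filter(list(id = "v", chrom = "chr1", start = s, end = s + 50),
                       "gA", loops, models,
                       max_anchor_gap = 200000)$is_distal_pair
  }, logical(1))
  lab_narrow <- vapply(starts, function(s) {
    distal_pair_filter(list(id = "v", chrom = "chr1", start = s, end = s + 50),
                       "gA", loops, models,
                       max_anchor_gap = 100000)$is_distal_pair
  }, logical(1))
  expect_true(all(lab_wide[lab_narrow]))  # narrow set is a subset
  # growing slop never removes anchor intersections
  hits10 <- vapply(starts, function(s) {
    anchor_intersect(list(start = s, end = s + 50), 400000, 410000, 10000)
  }, logical(1))
  hits20 <- vapply(starts, function(s) {
    anchor_intersect(list(start = s, end = s + 50), 400000, 410000, 20000)
  }, logical(1))
  expect_true(all(hits20[hits10]))
})

test_that("emitted distal pairs re-verify every criterion independently", {
  set.seed(82)
  co <- simulate_cohort(small_config(seed = 30, loop_density = 2))
  models <- co$genes
  vmeta <- co$variants$info
  genes <- utils::head(unique(co$loops$gene), 5)
  n_verified <- 0L
  for (g in genes) {
    gm <- models$genes[models$genes$id == g, ]
    cand <- vmeta[vmeta$chrom == gm$chrom, ]
    for (i in seq_len(nrow(cand))) {
      lab <- distal_pair_filter(cand[i, ], g, co$loops, models)
      if (!lab$is_distal_pair) next
      n_verified <- n_verified + 1L
      # independent re-check from raw coordinates
      gl <- co$loops[co$loops$gene == g, ]
      v <- cand[i, ]
      ve <- max(v$end, v$start + 1)
      gaps_d <- pmax(0, pmax(gl$d_start - ve, v$start - gl$d_end))
      l <- gl[which.min(gaps_d), ]
      vmid <- (v$start + ve) / 2
      expect_lt(abs(vmid - (l$d_start + l$d_end) / 2),
                abs(vmid - (l$p_start + l$p_end) / 2))
      pr <- models$promoters[models$promoters$gene_id == g, ]
      expect_gte(max(0, max(pr$start - ve, v$start - pr$end)), 50000)
      expect_lte(min(gaps_d), 200000)
      ex <- models$exons[models$exons$gene_id == g, ]
      expect_false(any(v$start < ex$end & ex$start < ve))
    }
  }
  expect_gt(n_verified, 0)
})

test_that("loop_distance_model rejects degenerate predictors and fits signal", {
  set.seed(83)
  n <- 3000
  dist_anchor <- runif(n, 0, 200000)
  pairs <- data.frame(
    is_eqtl = runif(n) < plogis(-1 - dist_anchor / 5e4),
    distance_to_distal_anchor = dist_anchor,
    distance_to_gene_body = runif(n, 100000, 900000),
    nmaf = runif(n, 0.05, 0.5),
    inside_loop = runif(n) < 0.5)
  m <- loop_distance_model(pairs)
  co <- m$combined
  est <- co$estimate[co$term == "distance_to_anchor"]
  expect_lt(est, 0)
  expect_lt(co$p[co$term == "distance_to_anchor"], 0.05)
  pairs$distance_to_distal_anchor <- 1000
  expect_error(loop_distance_model(pairs), "degenerate")
})

test_that("multigene loop strata partition the variants", {
  set.seed(84)
  n <- 500
  vs <- data.frame(
    n_looped_genes = sample(0:3, n, replace = TRUE),
    n_genes_tested = sample(3:8, n, replace = TRUE))
  vs$n_genes_tested <- pmax(vs$n_genes_tested, vs$n_looped_genes)
  vs$n_looped_egenes <- rbinom(n, vs$n_looped_genes, 0.5)
  vs$n_egenes <- vs$n_looped_egenes +
    rbinom(n, vs$n_genes_tested - vs$n_looped_genes, 0.1)
  vs$is_evariant <- vs$n_egenes > 0
  vs$is_lead <- vs$is_evariant & runif(n) < 0.5
  r <- multigene_loop_tests(vs)
  ks <- sort(unique(vs$n_looped_genes))
  counts <- vapply(ks, function(k) sum(vs$n_looped_genes == k), 0L)
  expect_equal(sum(counts), n)  # strata partition the tested variants
  # planted loop-mediated signal: looped variants are enriched
  expect_true(all(r$per_k$odds_ratio[r$per_k$outcome == "is_evariant"] > 1))
  st <- r$stratum_model
  expect_gt(st$estimate[st$term == "looped"], 0)
})

test_that("BEDPE round trip preserves loops", {
  co <- simulate_cohort(small_config(seed = 31))
  path <- tempfile(fileext = ".bedpe")
  write_loops_bedpe(co$loops, path)
  back <- read_loops_bedpe(path)
  expect_equal(back$p_start, co$loops$p_start)
  expect_equal(back$d_end, co$loops$d_end)
  expect_equal(back$gene, co$loops$gene)
})
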