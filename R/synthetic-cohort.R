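# Truth-annotated synthetic cohort generator.
#
# Emulates the data structure the eQTL pipeline assumes: a few hundred
# donors with family blocks in the kinship, twelve variant classes with
# caller-specific raw genotype encodings and class-specific length
# distributions, planted cis effects (exonic, promoter, proximal, and
# loop-distal mechanisms), dense latent expression confounders, a polygenic
# term with covariance proportional to the kinship, promoter-anchored
# chromatin loops, and tag SNVs in tunable LD with SVs/STRs carrying planted
# GWAS p-values. Every random draw flows from a single seed, so identical
# configurations give byte-identical outputs.

DEFAULT_CLASS_COUNTS <- c(SNV = 1200, indel = 300, DEL = 120, DUP = 40,
                          mCNV = 60, INV = 15, BND = 30, rMEI = 30,
                          ALU = 40, LINE1 = 15, SVA = 8, STR = 600)

# log-uniform length bounds per class (bp)
DEFAULT_LENGTH_BOUNDS <- list(
  SNV = c(1, 1), indel = c(1, 50), DEL = c(50, 1e6), DUP = c(50, 1e6),
  mCNV = c(50, 1e6), INV = c(50, 1e6), BND = c(1, 1), rMEI = c(200, 6000),
  ALU = c(280, 320), LINE1 = c(500, 6000), SVA = c(1000, 2000),
  STR = c(2, 100))

CLASS_ENCODING <- c(SNV = "biallelic_gt", indel = "biallelic_gt",
                    DEL = "allele_balance", DUP = "copy_number",
                    mCNV = "copy_number", INV = "allele_balance",
                    BND = "allele_balance", rMEI = "allele_balance",
                    ALU = "biallelic_gt", LINE1 = "biallelic_gt",
                    SVA = "biallelic_gt", STR = "str_gb")

#' Simulation configuration
#'
#' Validated parameter set for \code{\link{simulate_cohort}}. Defaults
#' reproduce the study conditions the pipeline targets: 398 donors with
#' family structure, a desk-scale gene and variant census with the twelve
#' variant classes in roughly their tested proportions, 30% of genes given
#' one planted cis effect with standardized |beta| in 0.5-1.5, dense latent
#' confounders, and a polygenic term explaining 20% of residual variance.
#'
#' @param n_samples number of donors.
#' @param n_genes number of genes on the single simulated chromosome.
#' @param genome_length chromosome length in bp.
#' @param class_counts named integer vector of variants per class.
#' @param length_bounds named list of c(min, max) log-uniform length bounds
#'   per class, in bp.
#' @param fraction_egenes fraction of genes given a planted cis effect.
#' @param base_effect central planted |beta| in standardized expression units.
#' @param beta_spread planted |beta| is uniform in
#'   \code{base_effect +/- beta_spread/2}.
#' @param length_slope optional additive term \code{length_slope *
#'   log10(length)} on planted |beta| (0 disables).
#' @param exon_mcnv_positive force positive beta for exonic mCNV effects
#'   (copy-gain increases expression).
#' @param n_confounders number of latent expression factors.
#' @param confounder_sd standard deviation of factor loadings.
#' @param polygenic_variance proportion of non-effect latent variance with
#'   covariance proportional to the kinship.
#' @param noise_sd residual latent noise sd; default
#'   \code{sqrt(1 - polygenic_variance)}.
#' @param family_block_sizes sizes of related family blocks in the kinship.
#' @param missing_rate per-entry genotype missingness probability.
#' @param loop_density expected chromatin loops per gene.
#' @param tag_fraction fraction of SVs/STRs given a panel tag SNV.
#' @param tag_r2_bounds bounds of the uniform target-r2 distribution.
#' @param trait_link_fraction fraction of tag SNVs given a genome-wide
#'   significant planted trait p-value.
#' @param n_traits number of traits in the GWAS panel.
#' @param seed integer RNG seed.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_samples = 398, n_genes = 200,
                              genome_length = 1e8,
                              class_counts = DEFAULT_CLASS_COUNTS,
                              length_bounds = DEFAULT_LENGTH_BOUNDS,
                              fraction_egenes = 0.3,
                              base_effect = 1.0, beta_spread = 1.0,
                              length_slope = 0, exon_mcnv_positive = TRUE,
                              n_confounders = 5, confounder_sd = 0.5,
                              polygenic_variance = 0.2, noise_sd = NULL,
                              family_block_sizes = rep(4L, 25L),
                              missing_rate = 0.002,
                              loop_density = 1.0, tag_fraction = 0.5,
                              tag_r2_bounds = c(0.4, 1.0),
                              trait_link_fraction = 0.1, n_traits = 50,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              genome_length = genome_length, class_counts = class_counts,
              length_bounds = length_bounds,
              fraction_egenes = fraction_egenes, base_effect = base_effect,
              beta_spread = beta_spread, length_slope = length_slope,
              exon_mcnv_positive = exon_mcnv_positive,
              n_confounders = as.integer(n_confounders),
              confounder_sd = confounder_sd,
              polygenic_variance = polygenic_variance,
              noise_sd = if (is.null(noise_sd)) sqrt(1 - polygenic_variance) else noise_sd,
              family_block_sizes = as.integer(family_block_sizes),
              missing_rate = missing_rate, loop_density = loop_density,
              tag_fraction = tag_fraction, tag_r2_bounds = tag_r2_bounds,
              trait_link_fraction = trait_link_fraction,
              n_traits = as.integer(n_traits), seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  chk_prop <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1)) {
      stop("configuration error: `", name, "` must be a proportion in [0, 1]")
    }
  }
  for (nm in c("fraction_egenes", "polygenic_variance", "missing_rate",
               "tag_fraction", "trait_link_fraction", "tag_r2_bounds")) chk_prop(nm)
  if (cfg$n_samples < 2) stop("configuration error: `n_samples` must be >= 2")
  if (cfg$n_genes < 1) stop("configuration error: `n_genes` must be >= 1")
  if (cfg$genome_length <= 0) stop("configuration error: `genome_length` must be positive")
  if (any(cfg$class_counts < 0) || is.null(names(cfg$class_counts)) ||
      !all(names(cfg$class_counts) %in% VARIANT_CLASSES)) {
    stop("configuration error: `class_counts` must be named by variant class")
  }
  for (cl in names(cfg$class_counts)) {
    b <- cfg$length_bounds[[cl]]
    if (is.null(b) || length(b) != 2 || any(b <= 0) || b[1] > b[2]) {
      stop("configuration error: `length_bounds` invalid for class ", cl)
    }
  }
  if (length(cfg$family_block_sizes) &&
      cfg$n_samples < 2 * max(cfg$family_block_sizes)) {
    stop("configuration error: `n_samples` must be >= 2 x max family block")
  }
  if (cfg$tag_r2_bounds[1] > cfg$tag_r2_bounds[2]) {
    stop("configuration error: `tag_r2_bounds` must be increasing")
  }
  if (cfg$noise_sd < 0) stop("configuration error: `noise_sd` must be >= 0")
  invisible(cfg)
}

#' Simulate a block-family kinship matrix
#'
#' Block-diagonal family relatedness (coefficient 0.5 within blocks) plus a
#' scaled identity, normalized to unit mean diagonal. Positive semi-definite
#' by construction.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param rng_state optional integer seed.
#' @return samples x samples kinship matrix with sample-id dimnames.
#' @export
simulate_kinship <- function(config, rng_state = NULL) {
  if (!is.null(rng_state)) set.seed(rng_state)
  n <- config$n_samples
  ids <- sample_ids(n)
  K <- diag(n)
  pos <- 1L
  for (b in config$family_block_sizes) {
    if (pos + b - 1L > n) break
    idx <- pos:(pos + b - 1L)
    K[idx, idx] <- 0.5
    diag(K)[idx] <- 1
    pos <- pos + b
  }
  K <- K / mean(diag(K))
  dimnames(K) <- list(ids, ids)
  K
}

sample_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate gene models
#'
#' Places genes along one chromosome with log-uniform body lengths, random
#' strands, 2-12 exons, strand-aware promoters, Gencode-style gene types and
#' constraint scores.
#'
#' @inheritParams simulate_kinship
#' @return a \code{gene_models} object (see \code{\link{gene_models}}).
#' @export
simulate_gene_models <- function(config, rng_state = NULL) {
  if (!is.null(rng_state)) set.seed(rng_state)
  n <- config$n_genes
  ids <- sprintf("G%04d", seq_len(n))
  body_len <- round(exp(stats::runif(n, log(5e3), log(2e5))))
  start <- sort(round(stats::runif(n, 1e6, config$genome_length - 1e6 - max(body_len))))
  end <- start + body_len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end - 1)
  gene_type <- sample(c("protein_coding", "pseudogene", "lincRNA", "antisense",
                        "other"), n, replace = TRUE,
                      prob = c(0.6, 0.15, 0.1, 0.1, 0.05))
  cons <- t(vapply(seq_len(n), function(i) {
    x <- stats::rgamma(3, shape = c(0.4, 0.6, 0.8))
    x / sum(x)
  }, numeric(3)))
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(2:12, 1)
    # split the body into 2k+1 segments; every second segment is an exon
    cuts <- sort(stats::runif(2 * k, start[i] + 1, end[i] - 1))
    es <- round(cuts[seq(1, 2 * k, by = 2)])
    ee <- round(cuts[seq(2, 2 * k, by = 2)])
    ok <- ee > es
    data.frame(gene_id = ids[i], start = es[ok], end = ee[ok],
               stringsAsFactors = FALSE)
  }))
  genes <- data.frame(id = ids, chrom = "chr1", strand = strand,
                      start = start, end = end, tss = tss,
                      gene_type = gene_type,
                      pli = cons[, 1], prec = cons[, 2], pnull = cons[, 3],
                      stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

# log-uniform lengths per class
draw_lengths <- function(n, bounds) {
  round(exp(stats::runif(n, log(bounds[1]), log(bounds[2]))))
}

#' Simulate caller-style genotypes
#'
#' Generates variant records for every configured class with raw fields in
#' the caller-specific encoding: STRs as pairs of per-allele bp length
#' differences (GB style), duplications and multiallelic CNVs as integer
#' diploid copy numbers (mCNVs always realize at least 3 distinct copy
#' numbers), deletions/inversions/break-ends/rMEIs as allele-balance
#' fractions, and MEIs/SNVs/indels as 0/0-0/1-1/1 genotypes. A configurable
#' fraction of entries is set missing. The underlying continuous genotype
#' value used to plant effects is attached as attribute
#' \code{underlying} (variants x samples).
#'
#' @inheritParams simulate_kinship
#' @return a \code{\link{variant_records}} object with attribute
#'   \code{underlying}.
#' @export
simulate_genotypes <- function(config, rng_state = NULL) {
  if (!is.null(rng_state)) set.seed(rng_state)
  n <- config$n_samples
  counts <- config$class_counts[config$class_counts > 0]
  total <- sum(counts)
  cls <- rep(names(counts), counts)
  ids <- sprintf("V%05d", seq_len(total))
  lens <- afs <- numeric(total)
  raw <- matrix(".", total, n, dimnames = list(ids, sample_ids(n)))
  underlying <- matrix(0, total, n, dimnames = dimnames(raw))
  for (i in seq_len(total)) {
    cl <- cls[i]
    af <- stats::runif(1, 0.08, 0.5)
    enc <- CLASS_ENCODING[[cl]]
    len <- draw_lengths(1, config$length_bounds[[cl]])
    if (enc == "biallelic_gt") {
      g <- stats::rbinom(n, 2, af)
      raw[i, ] <- c("0/0", "0/1", "1/1")[g + 1]
      underlying[i, ] <- g
    } else if (enc == "allele_balance") {
      g <- stats::rbinom(n, 2, af)
      ab <- pmin(pmax(g / 2 + stats::rnorm(n, 0, 0.05), 0), 1)
      raw[i, ] <- formatC(round(ab, 3), format = "f", digits = 3)
      underlying[i, ] <- ab
    } else if (enc == "copy_number") {
      if (cl == "mCNV") {
        k <- sample(3:5, 1)
        allele_cn <- sort(sample(0:4, k))
        freq <- as.numeric(stats::rgamma(k, 1.5)); freq <- freq / sum(freq)
        cn <- replicate(50, {
          a1 <- sample(allele_cn, n, replace = TRUE, prob = freq)
          a2 <- sample(allele_cn, n, replace = TRUE, prob = freq)
          a1 + a2
        }, simplify = FALSE)
        cn <- cn[[which(vapply(cn, function(x) length(unique(x)), 0L) >= 3)[1]]]
      } else { # DUP
        cn <- 2 + stats::rbinom(n, 2, af)
      }
      raw[i, ] <- as.character(cn)
      underlying[i, ] <- cn
    } else { # str_gb
      motif <- sample(2:4, 1)
      k <- sample(2:6, 1)
      diffs <- sort(sample(setdiff(-3:3, 0), k - 1)) * motif
      alleles <- c(0, diffs)
      len <- max(abs(alleles))
      if (len == 0) len <- motif
      freq <- as.numeric(stats::rgamma(k, 1.5)); freq <- freq / sum(freq)
      a1 <- sample(alleles, n, replace = TRUE, prob = freq)
      a2 <- sample(alleles, n, replace = TRUE, prob = freq)
      raw[i, ] <- paste0(a1, "|", a2)
      underlying[i, ] <- a1 + a2
    }
    lens[i] <- len
    afs[i] <- af
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(total * n) < config$missing_rate, total, n)
    raw[miss] <- "."
  }
  start <- round(stats::runif(total, 1, config$genome_length - max(lens) - 1))
  spanning <- cls %in% c("DEL", "DUP", "mCNV", "INV", "rMEI", "STR", "SNV", "indel")
  end <- ifelse(spanning, start + lens, start)  # MEI/BND insertion points
  info <- data.frame(id = ids, variant_class = cls, chrom = "chr1",
                     start = start, end = end, length = lens,
                     encoding = unname(CLASS_ENCODING[cls]),
                     cluster_id = NA_character_, stringsAsFactors = FALSE)
  # a few redundancy clusters among SVs (same call from multiple callers)
  sv_idx <- which(!(cls %in% c("SNV", "indel", "STR")))
  if (length(sv_idx) >= 10) {
    cluster_members <- sample(sv_idx, min(10, length(sv_idx)))
    info$cluster_id[cluster_members] <- paste0("RC", rep(1:5, length.out = length(cluster_members)))
  }
  rec <- variant_records(info, raw)
  attr(rec, "underlying") <- underlying
  attr(rec, "alt_af") <- afs  # drawn alternate-allele frequency per variant
  rec
}

# Choose eGenes, mechanisms, and planted betas; relocates the chosen variant
# so the mechanism really holds (positions are independent of genotypes).
# Only variants that pass the downstream inclusion filters (non-mode allele
# frequency, STR call rate) are eligible, so every planted effect is
# recoverable in principle.
plant_effects <- function(config, genes, variants) {
  n_eg <- round(config$fraction_egenes * config$n_genes)
  empty <- data.frame(gene = character(), variant = character(),
                      beta = numeric(), mechanism = character(),
                      stringsAsFactors = FALSE)
  if (n_eg == 0) return(list(planted = empty, info = variants$info))
  info <- variants$info
  eligible <- vapply(seq_len(nrow(info)), function(i) {
    raw_i <- variants$raw[i, ]
    cr <- mean(!is_missing_field(raw_i))
    if (cr == 0) return(FALSE)
    if (info$variant_class[i] == "STR" && cr < 0.99) return(FALSE)
    non_mode_allele_freq(raw_i, info$encoding[i]) >= 0.06
  }, logical(1))
  gdf <- genes$genes
  egenes <- sample(gdf$id, n_eg)
  mechanisms <- rep(c("exonic", "promoter", "proximal", "loop_distal"),
                    length.out = n_eg)
  used <- character(0)
  rows <- vector("list", n_eg)
  for (j in seq_len(n_eg)) {
    g <- gdf[gdf$id == egenes[j], ]
    mech <- mechanisms[j]
    pool <- setdiff(info$id[eligible], used)
    if (mech == "exonic" && config$exon_mcnv_positive && j %% 4 == 1) {
      mpool <- intersect(pool, info$id[info$variant_class == "mCNV"])
      if (length(mpool)) pool <- mpool
    }
    vid <- sample(pool, 1)
    i <- match(vid, info$id)
    len <- info$length[i]
    span <- info$end[i] > info$start[i]
    new_start <- switch(mech,
      exonic = {
        ex <- genes$exons[genes$exons$gene_id == g$id, ]
        e <- ex[sample(nrow(ex), 1), ]
        round(stats::runif(1, e$start, max(e$start + 1, e$end - 1)))
      },
      promoter = {
        pr <- promoter_interval(g$tss, g$strand)
        round(stats::runif(1, pr[1], pr[2] - 1))
      },
      proximal = {
        g$tss + round(stats::runif(1, -1e5, 1e5))
      },
      loop_distal = {
        off <- round(stats::runif(1, 6e4, 2.4e5))
        if (stats::runif(1) < 0.5) g$start - off - len else g$end + off
      })
    new_start <- max(1, min(new_start, config$genome_length - len - 1))
    info$start[i] <- new_start
    info$end[i] <- if (span) new_start + len else new_start
    abs_beta <- config$base_effect +
      config$length_slope * log10(max(len, 1)) +
      stats::runif(1, -config$beta_spread / 2, config$beta_spread / 2)
    abs_beta <- max(abs_beta, 0.1)
    sign <- if (mech == "exonic" && info$variant_class[i] == "mCNV" &&
                config$exon_mcnv_positive) 1 else sample(c(-1, 1), 1)
    used <- c(used, vid)
    rows[[j]] <- data.frame(gene = g$id, variant = vid, beta = sign * abs_beta,
                            mechanism = mech, stringsAsFactors = FALSE)
  }
  list(planted = do.call(rbind, rows), info = info)
}

#' Simulate chromatin loops
#'
#' One promoter-capture loop set: each loop's promoter anchor overlaps its
#' gene's promoter; distal anchors of genes with a planted loop-distal
#' effect are centered on the planted variant; a fraction of distal anchors
#' is shared between neighbouring genes (high-complexity anchors).
#'
#' @param genes a \code{gene_models} object.
#' @param variants a \code{\link{variant_records}} object.
#' @param truth planted-effect data.frame (gene, variant, mechanism).
#' @param config a \code{\link{simulation_config}}.
#' @param rng_state optional integer seed.
#' @return data.frame of loops: \code{loop_id}, \code{gene},
#'   \code{chrom}, \code{p_start}, \code{p_end}, \code{d_start},
#'   \code{d_end}.
#' @export
simulate_loops <- function(genes, variants, truth, config, rng_state = NULL) {
  if (!is.null(rng_state)) set.seed(rng_state)
  gdf <- genes$genes
  rows <- list()
  prev_anchor <- NULL
  for (i in seq_len(nrow(gdf))) {
    g <- gdf[i, ]
    planted <- truth[truth$gene == g$id & truth$mechanism == "loop_distal", ]
    n_loops <- stats::rpois(1, config$loop_density) + (nrow(planted) > 0)
    if (n_loops == 0) next
    pr <- promoter_interval(g$tss, g$strand)
    for (l in seq_len(n_loops)) {
      p_start <- pr[1] - round(stats::runif(1, 0, 2000))
      p_end <- pr[2] + round(stats::runif(1, 0, 2000))
      if (l == 1 && nrow(planted) > 0) {
        v <- variants$info[variants$info$id == planted$variant[1], ]
        mid <- (v$start + max(v$end, v$start + 1)) / 2
        half <- round(stats::runif(1, 2500, 5000))
        d_start <- round(mid - half); d_end <- round(mid + half)
      } else if (!is.null(prev_anchor) && stats::runif(1) < 0.2 &&
                 abs(prev_anchor[1] - g$tss) < 4e5) {
        d_start <- prev_anchor[1]; d_end <- prev_anchor[2]  # shared anchor
      } else {
        off <- round(stats::runif(1, 6e4, 4e5)) * sample(c(-1, 1), 1)
        d_start <- g$tss + off; d_end <- d_start + round(stats::runif(1, 5000, 10000))
      }
      d_start <- max(1, d_start); d_end <- max(d_start + 1000, d_end)
      # anchors must be disjoint
      if (d_start < p_end && p_start < d_end) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$id, chrom = g$chrom, p_start = p_start, p_end = p_end,
        d_start = d_start, d_end = d_end, stringsAsFactors = FALSE)
      prev_anchor <- c(d_start, d_end)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(loop_id = character(), gene = character(),
                      chrom = character(), p_start = numeric(),
                      p_end = numeric(), d_start = numeric(),
                      d_end = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  cbind(loop_id = sprintf("L%04d", seq_len(nrow(out))), out,
        stringsAsFactors = FALSE)
}

#' Simulate expression from planted effects
#'
#' Latent expression per gene is the sum of the planted genetic effect on
#' the standardized underlying dosage, dense confounder contributions, a
#' polygenic term with covariance proportional to the kinship, and i.i.d.
#' noise. TPM is a fixed monotone transform of the latent scale:
#' \code{TPM = max(exp(latent + baseline) - offset, 0)} with gene-specific
#' baselines, so the pipeline's log/standardize step recovers the latent
#' ordering on the expressed range.
#'
#' @param variants a \code{\link{variant_records}} object carrying the
#'   \code{underlying} attribute.
#' @param truth planted-effect data.frame (gene, variant, beta).
#' @param kinship samples x samples PSD kinship matrix.
#' @param config a \code{\link{simulation_config}}.
#' @param genes a \code{gene_models} object (gene ids).
#' @param rng_state optional integer seed.
#' @return list with \code{tpm} (genes x samples), \code{latent},
#'   \code{confounder_loadings}, \code{baselines}.
#' @export
simulate_expression <- function(variants, truth, kinship, config, genes,
                                rng_state = NULL) {
  if (!is.null(rng_state)) set.seed(rng_state)
  ev <- eigen(kinship, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("kinship matrix is not positive semi-definite")
  K_sqrt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  n <- config$n_samples
  ng <- config$n_genes
  ids <- genes$genes$id
  underlying <- attr(variants, "underlying")
  nf <- config$n_confounders
  loadings <- matrix(stats::rnorm(ng * max(nf, 1), 0, config$confounder_sd),
                     ng, max(nf, 1), dimnames = list(ids, NULL))
  factors <- matrix(stats::rnorm(max(nf, 1) * n), max(nf, 1), n)
  latent <- matrix(0, ng, n, dimnames = list(ids, colnames(kinship)))
  if (nf > 0) latent <- loadings[, seq_len(nf), drop = FALSE] %*%
    factors[seq_len(nf), , drop = FALSE]
  if (config$polygenic_variance > 0) {
    poly <- matrix(stats::rnorm(ng * n), ng, n) %*% K_sqrt *
      sqrt(config$polygenic_variance)
    latent <- latent + poly
  }
  if (config$noise_sd > 0) {
    latent <- latent + matrix(stats::rnorm(ng * n, 0, config$noise_sd), ng, n)
  }
  for (j in seq_len(nrow(truth))) {
    d <- underlying[truth$variant[j], ]
    if (stats::sd(d) > 0) {
      latent[truth$gene[j], ] <- latent[truth$gene[j], ] +
        truth$beta[j] * as.numeric(scale(d))
    }
  }
  baselines <- stats::rnorm(ng, 1.5, 1.5)
  baselines[ids %in% truth$gene] <- pmax(baselines[ids %in% truth$gene], 1.5)
  tpm <- pmax(exp(latent + baselines) - 0.25, 0)
  dimnames(latent) <- dimnames(tpm) <- list(ids, colnames(kinship))
  list(tpm = tpm, latent = latent,
       confounder_loadings = loadings, baselines = baselines)
}

#' Simulate a GWAS panel with tunable LD tags
#'
#' Places tag SNVs within 50 kb of a random subset of SVs/STRs with dosages
#' equal to the standardized SV dosage plus Gaussian noise calibrated so the
#' expected squared correlation hits a target drawn from
#' \code{tag_r2_bounds}. Each tag carries per-trait p-values; a fraction of
#' tags receives a planted genome-wide significant p (< 5e-8), and those
#' (tag, trait) pairs are recorded as truth trait links.
#'
#' @inheritParams simulate_loops
#' @return list with \code{snvs} (id, pos, target_r2, source_variant),
#'   \code{dosages} (tags x samples), \code{traits} (snv, trait, p) and
#'   \code{trait_links} truth data.frame.
#' @export
simulate_gwas_panel <- function(variants, config, rng_state = NULL) {
  if (!is.null(rng_state)) set.seed(rng_state)
  info <- variants$info
  underlying <- attr(variants, "underlying")
  svstr <- info[!(info$variant_class %in% c("SNV", "indel")), ]
  n_tag <- round(config$tag_fraction * nrow(svstr))
  empty <- list(snvs = data.frame(id = character(), pos = numeric(),
                                  target_r2 = numeric(),
                                  source_variant = character(),
                                  stringsAsFactors = FALSE),
                dosages = matrix(0, 0, config$n_samples),
                traits = data.frame(snv = character(), trait = character(),
                                    p = numeric(), stringsAsFactors = FALSE),
                trait_links = data.frame(snv = character(), trait = character(),
                                         stringsAsFactors = FALSE))
  if (n_tag == 0) return(empty)
  chosen <- svstr[sample(nrow(svstr), n_tag), ]
  n <- config$n_samples
  dos <- matrix(0, n_tag, n,
                dimnames = list(sprintf("TAG%04d", seq_len(n_tag)),
                                sample_ids(n)))
  pos <- numeric(n_tag)
  r2 <- stats::runif(n_tag, config$tag_r2_bounds[1], config$tag_r2_bounds[2])
  for (i in seq_len(n_tag)) {
    g <- underlying[chosen$id[i], ]
    if (stats::sd(g) == 0) g <- g + stats::rnorm(n, 0, 1e-6)
    z <- as.numeric(scale(g))
    noise_sd <- if (r2[i] >= 1) 0 else sqrt(1 / r2[i] - 1)
    dos[i, ] <- z + stats::rnorm(n, 0, noise_sd)
    pos[i] <- max(1, chosen$start[i] + round(stats::runif(1, -5e4, 5e4)))
  }
  snvs <- data.frame(id = rownames(dos), pos = pos, target_r2 = r2,
                     source_variant = chosen$id, stringsAsFactors = FALSE)
  # per-trait p-values: 3 random traits per tag, uniform p
  traits <- do.call(rbind, lapply(seq_len(n_tag), function(i) {
    tr <- sample(config$n_traits, 3)
    data.frame(snv = snvs$id[i], trait = sprintf("T%03d", tr),
               p = stats::runif(3), stringsAsFactors = FALSE)
  }))
  n_linked <- round(config$trait_link_fraction * n_tag)
  links <- empty$trait_links
  if (n_linked > 0) {
    linked <- sample(n_tag, n_linked)
    planted <- data.frame(snv = snvs$id[linked],
                          trait = sprintf("T%03d", sample(config$n_traits,
                                                          n_linked, replace = TRUE)),
                          p = 10^stats::runif(n_linked, -12, -8.5),
                          stringsAsFactors = FALSE)
    traits <- rbind(traits, planted)
    links <- planted[, c("snv", "trait")]
  }
  list(snvs = snvs, dosages = dos, traits = traits, trait_links = links)
}

#' Simulate a complete truth-annotated cohort
#'
#' Top-level generator: kinship, gene models, variant genotypes, planted cis
#' effects, chromatin loops, expression and a GWAS panel, all mutually
#' consistent (identical sample ids throughout; truth references existing
#' ids) and deterministic given the configured seed.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return object of class \code{sv_cohort}: list with \code{config},
#'   \code{samples}, \code{kinship}, \code{genes}, \code{variants},
#'   \code{expression} (TPM genes x samples), \code{loops}, \code{gwas},
#'   and \code{truth} (planted effects, confounder loadings, looped pairs,
#'   trait links).
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_samples = 40, n_genes = 10,
#'   class_counts = c(SNV = 50, STR = 20, DEL = 10), seed = 7))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  kinship <- simulate_kinship(config)
  genes <- simulate_gene_models(config)
  variants <- simulate_genotypes(config)
  planted <- plant_effects(config, genes, variants)
  underlying <- attr(variants, "underlying")
  variants <- variant_records(planted$info, variants$raw)
  attr(variants, "underlying") <- underlying
  loops <- simulate_loops(genes, variants, planted$planted, config)
  expr <- simulate_expression(variants, planted$planted, kinship, config, genes)
  gwas <- simulate_gwas_panel(variants, config)
  looped <- planted$planted[planted$planted$mechanism == "loop_distal",
                            c("variant", "gene")]
  structure(list(config = config, samples = sample_ids(config$n_samples),
                 kinship = kinship, genes = genes, variants = variants,
                 expression = expr$tpm, loops = loops, gwas = gwas,
                 truth = list(planted_effects = planted$planted,
                              confounder_loadings = expr$confounder_loadings,
                              looped_pairs = looped,
                              trait_links = gwas$trait_links,
                              latent = expr$latent)),
            class = "sv_cohort")
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat("synthetic cohort:", x$config$n_samples, "samples,",
      x$config$n_genes, "genes,", nrow(x$variants$info), "variants\n")
  cat("  planted effects:", nrow(x$truth$planted_effects),
      "| loops:", nrow(x$loops),
      "| GWAS tags:", nrow(x$gwas$snvs), "\n")
  invisible(x)
}
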