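# cis-eQTL mapping with a linear mixed model.
#
# Per gene the null model is y = C a + u + e with cov(u) = sigma_g^2 K and
# cov(e) = sigma_e^2 I. One eigendecomposition of the kinship matrix K
# rotates the model to independent observations; the variance ratio
# delta = sigma_e^2 / sigma_g^2 is estimated once per gene under the null by
# maximum likelihood and reused for every cis variant (standard fast-LMM
# practice). Each variant adds a fixed effect g b; significance is a
# 1-df likelihood-ratio test. Gene-level multiple testing uses genotype
# permutations (all cis variants permuted jointly, preserving local LD),
# summarized either by a maximum-likelihood beta fit to the permutation
# minima or by the empirical rank formula; Storey q-values control FDR
# across genes.

#' Filter and standardize expression
#'
#' Keeps genes expressed (TPM > 0) in more than \code{min_expressed_fraction}
#' of samples and with mean TPM above \code{min_tpm_among_expressers} among
#' the samples expressing them, then log-transforms (log2(TPM + 1)) and
#' standardizes each kept gene to mean 0, sd 1.
#'
#' @param tpm genes x samples matrix of non-negative TPM values.
#' @param min_expressed_fraction expression-breadth threshold (default 0.20,
#'   strict inequality).
#' @param min_tpm_among_expressers mean-TPM threshold among expressing
#'   samples (default 0.5, strict inequality).
#' @return list with \code{processed} (kept genes x samples, standardized)
#'   and \code{kept} (gene ids).
#' @export
prepare_expression <- function(tpm, min_expressed_fraction = 0.20,
                               min_tpm_among_expressers = 0.5) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  expressed_frac <- rowMeans(tpm > 0)
  mean_among <- apply(tpm, 1, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  keep <- expressed_frac > min_expressed_fraction &
    mean_among > min_tpm_among_expressers
  if (!any(keep)) stop("no genes pass the expression filters")
  lg <- log2(tpm[keep, , drop = FALSE] + 1)
  processed <- t(scale(t(lg)))
  # genes with zero variance after log cannot be standardized
  ok <- apply(processed, 1, function(v) all(is.finite(v)))
  processed <- processed[ok, , drop = FALSE]
  if (nrow(processed) == 0) stop("no genes pass the expression filters")
  list(processed = processed, kept = rownames(processed))
}

#' Expression principal components
#'
#' Sample-level principal components of the processed expression matrix, a
#' stand-in for latent expression confounders when no external covariates
#' are supplied.
#'
#' @param processed standardized genes x samples matrix.
#' @param n number of components (default 10).
#' @return samples x n matrix of PC scores.
#' @export
expression_pcs <- function(processed, n = 10) {
  n <- min(n, nrow(processed) - 1L, ncol(processed) - 1L)
  pc <- stats::prcomp(t(processed), center = TRUE, scale. = FALSE)
  pc$x[, seq_len(n), drop = FALSE]
}

#' Cis-window variant lookup
#'
#' Returns the ids of variants whose interval intersects the window spanning
#' \code{window} bp up- and downstream of the gene body, i.e.
#' [gene_start - window, gene_end + window). Zero-width insertion intervals
#' are treated as 1 bp points.
#'
#' @param gene one-row data.frame (or list) with \code{chrom}, \code{start},
#'   \code{end} of the gene body (0-based half-open).
#' @param variants data.frame with \code{id}, \code{chrom}, \code{start},
#'   \code{end} columns (e.g. \code{dosage_matrix$variants}).
#' @param window cis-window half-width in bp (default 1e6).
#' @return character vector of variant ids.
#' @export
cis_pairs <- function(gene, variants, window = 1e6) {
  win_start <- gene$start - window
  win_end <- gene$end + window
  v_end <- pmax(variants$end, variants$start + 1)  # insertions as points
  hit <- variants$chrom == gene$chrom &
    variants$start < win_end & v_end > win_start
  variants$id[hit]
}

# Null-model ML fit after rotation by the eigenvectors of K.
# Profiles the likelihood over log(delta); sigma_g^2 has a closed form.
lmm_null_fit <- function(y, C, K, eig = NULL) {
  n <- length(y)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Ct <- crossprod(U, C)

  neg_ll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (lambda + delta)
    sw <- sqrt(w)
    yw <- yt * sw
    Cw <- Ct * sw
    fit <- stats::lm.fit(Cw, yw)
    rss <- sum(fit$residuals^2)
    sigma_g2 <- rss / n
    0.5 * (n * log(2 * pi) + n * log(sigma_g2) - sum(log(w)) + n)
  }
  opt <- stats::optimize(neg_ll, interval = c(-12, 12))
  delta <- exp(opt$minimum)
  w <- 1 / (lambda + delta)
  sw <- sqrt(w)
  yw <- yt * sw
  Cw <- Ct * sw
  qrC <- qr(Cw)
  if (qrC$rank < ncol(Cw)) stop("covariate matrix is rank deficient")
  Q <- qr.Q(qrC)
  yperp <- yw - Q %*% crossprod(Q, yw)
  rss0 <- sum(yperp^2)
  sigma_g2 <- rss0 / n
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma_g2) - sum(log(w)) + n)
  list(U = U, lambda = lambda, delta = delta, sw = sw, Q = Q,
       yperp = yperp, rss0 = rss0, n = n,
       vc = list(sigma_g2 = sigma_g2, sigma_e2 = sigma_g2 * delta,
                 delta = delta, loglik = loglik))
}

# Core per-variant quantities given the rotated null fit. G is samples x
# variants on the original (unrotated) sample order. Returns bare vectors
# (this runs once per permutation, so it avoids data.frame overhead).
lmm_variant_core <- function(null_fit, G, perm = NULL) {
  if (!is.null(perm)) G <- G[perm, , drop = FALSE]
  Gt <- crossprod(null_fit$U, G) * null_fit$sw
  Gperp <- Gt - null_fit$Q %*% crossprod(null_fit$Q, Gt)
  denom <- colSums(Gperp^2)
  cross <- drop(crossprod(Gperp, null_fit$yperp))
  n <- null_fit$n
  ok <- denom > n * 1e-12
  beta <- se <- lrt <- p <- rep(NA_real_, ncol(G))
  beta[ok] <- cross[ok] / denom[ok]
  rss1 <- pmax(null_fit$rss0 - beta^2 * denom, .Machine$double.xmin)
  lrt[ok] <- pmax(n * log(null_fit$rss0 / rss1[ok]), 0)
  se[ok] <- sqrt((rss1[ok] / n) / denom[ok])
  p[ok] <- stats::pchisq(lrt[ok], df = 1, lower.tail = FALSE)
  list(beta = beta, se = se, lrt = lrt, p = p, ok = ok)
}

# minimum nominal p across cis variants for one genotype permutation
lmm_min_perm_p <- function(null_fit, G, perm) {
  Gt <- crossprod(null_fit$U, G[perm, , drop = FALSE]) * null_fit$sw
  Gperp <- Gt - null_fit$Q %*% crossprod(null_fit$Q, Gt)
  denom <- colSums(Gperp^2)
  ok <- denom > null_fit$n * 1e-12
  if (!any(ok)) return(NA_real_)
  explained <- (drop(crossprod(Gperp, null_fit$yperp))[ok])^2 / denom[ok]
  rss1 <- pmax(null_fit$rss0 - explained, .Machine$double.xmin)
  lrt_max <- null_fit$n * log(null_fit$rss0 / min(rss1))
  stats::pchisq(max(lrt_max, 0), df = 1, lower.tail = FALSE)
}

lmm_variant_stats <- function(null_fit, G, perm = NULL) {
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  st <- lmm_variant_core(null_fit, G, perm)
  data.frame(variant = colnames(G), beta = st$beta, se = st$se,
             lrt = st$lrt, p = st$p, failed = !st$ok,
             stringsAsFactors = FALSE)
}

#' Linear-mixed-model association scan for one gene
#'
#' Fits the null model \code{y = C a + u + e} with \code{cov(u) =
#' sigma_g^2 K} by maximum likelihood via one eigendecomposition of K, then
#' tests each cis variant as a fixed effect reusing the null variance ratio.
#' Significance per variant is a likelihood-ratio test against a chi-square
#' with 1 df, clipped at 0.
#'
#' @param y numeric vector: one processed expression row (length n samples).
#' @param G samples x variants dosage matrix for the gene's cis window.
#' @param C samples x covariates matrix; an intercept column is added if
#'   absent.
#' @param K samples x samples kinship matrix (symmetric PSD).
#' @param eig optional precomputed \code{eigen(K, symmetric = TRUE)}, shared
#'   across genes.
#' @return list with \code{associations} (data.frame: variant, beta, se,
#'   lrt, p, failed flag) and \code{vc} (variance components incl. the null
#'   log-likelihood), plus the internal null fit for reuse.
#' @export
lmm_scan <- function(y, G, C = NULL, K, eig = NULL) {
  n <- length(y)
  G <- as.matrix(G)
  if (nrow(G) != n) stop("G must be samples x variants with nrow = length(y)")
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  C <- build_covariates(C, n)
  if (!all(dim(K) == c(n, n))) stop("kinship dimension mismatch")
  null_fit <- lmm_null_fit(y, C, K, eig = eig)
  assoc <- lmm_variant_stats(null_fit, G)
  list(associations = assoc, vc = null_fit$vc, null_fit = null_fit)
}

build_covariates <- function(C, n) {
  if (is.null(C)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  C <- as.matrix(C)
  if (nrow(C) != n) stop("covariate matrix has wrong number of samples")
  has_intercept <- any(apply(C, 2, function(col) all(col == col[1]) && col[1] != 0))
  if (!has_intercept) C <- cbind(intercept = 1, C)
  C
}

#' Permutation-based gene-level p-value adjustment
#'
#' Re-runs the cis scan on permutations of the genotype matrix (sample rows
#' permuted jointly across all cis variants, keeping expression, covariates
#' and kinship fixed) and records the minimum nominal p per permutation. The
#' default adjustment fits a beta distribution to the permutation minima by
#' maximum likelihood and evaluates its CDF at the observed minimum;
#' \code{mode = "empirical"} uses the rank formula
#' \code{(1 + #\{minima <= observed\}) / (n_perm + 1)}. If the beta fit
#' fails the empirical formula is used. The adjusted p is floored at the
#' observed minimum nominal p.
#'
#' @param scan result of \code{\link{lmm_scan}} for the gene.
#' @param G the same samples x variants dosage matrix passed to the scan.
#' @param n_perm number of permutations (default 1000; fewer than 100 draws
#'   a warning).
#' @param mode "beta" or "empirical".
#' @param rng_state optional integer seed making the permutations
#'   reproducible without touching the global RNG stream outside this call.
#' @return list with \code{p_adjusted}, \code{p_min_observed},
#'   \code{perm_minima}, \code{mode_used}, and the beta parameters when
#'   fitted.
#' @export
permutation_adjust <- function(scan, G, n_perm = 1000,
                               mode = c("beta", "empirical"),
                               rng_state = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 100) warning("n_perm < 100: adjusted p-values will be coarse")
  if (!is.null(rng_state)) set.seed(rng_state)
  null_fit <- scan$null_fit
  G <- as.matrix(G)
  n <- null_fit$n
  obs <- min(scan$associations$p, na.rm = TRUE)
  minima <- vapply(seq_len(n_perm), function(b) {
    lmm_min_perm_p(null_fit, G, perm = sample.int(n))
  }, 0)
  minima <- minima[!is.na(minima)]
  n_perm <- length(minima)
  empirical <- (1 + sum(minima <= obs)) / (n_perm + 1)
  out <- list(p_min_observed = obs, perm_minima = minima, n_perm = n_perm)
  if (mode == "beta") {
    bf <- fit_beta_ml(minima)
    if (is.null(bf)) {
      out$p_adjusted <- empirical
      out$mode_used <- "empirical"
    } else {
      out$p_adjusted <- stats::pbeta(obs, bf$shape1, bf$shape2)
      out$mode_used <- "beta"
      out$beta_shape <- bf
    }
  } else {
    out$p_adjusted <- empirical
    out$mode_used <- "empirical"
  }
  out$p_adjusted <- min(max(out$p_adjusted, obs, .Machine$double.xmin), 1)
  out
}

# ML beta fit; NULL on failure so callers can fall back to the empirical rank.
fit_beta_ml <- function(x) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= 0) return(NULL)
  common <- m * (1 - m) / v - 1
  init <- c(max(m * common, 1e-3), max((1 - m) * common, 1e-3))
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  opt <- tryCatch(stats::optim(log(init), nll), error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) return(NULL)
  list(shape1 = exp(opt$par[1]), shape2 = exp(opt$par[2]))
}

#' Call eGenes at an FDR threshold
#'
#' Converts gene-level permutation-adjusted p-values to Storey q-values and
#' flags genes with q below the FDR threshold as eGenes. The lead eVariant
#' per gene is the cis variant with the smallest nominal p, ties broken by
#' smaller distance to the TSS and then lexicographic variant id.
#'
#' @param gene_results data.frame with one row per tested gene: \code{gene},
#'   \code{p_adjusted}, \code{lead_variant}, \code{beta_lead}, \code{p_lead}.
#' @param fdr q-value threshold (default 0.05).
#' @return the input with \code{q_value} and logical \code{egene} columns,
#'   sorted by q then gene id.
#' @export
call_egenes <- function(gene_results, fdr = 0.05) {
  if (nrow(gene_results) == 0) stop("no gene results supplied")
  qv <- storey_qvalues(gene_results$p_adjusted)
  gene_results$q_value <- qv$q
  gene_results$egene <- gene_results$q_value < fdr
  attr(gene_results, "pi0") <- qv$pi0
  gene_results[order(gene_results$q_value, gene_results$gene), ]
}

pick_lead <- function(assoc, variants, tss) {
  ok <- !assoc$failed
  a <- assoc[ok, , drop = FALSE]
  if (nrow(a) == 0) return(NULL)
  meta <- variants[match(a$variant, variants$id), ]
  v_end <- pmax(meta$end, meta$start + 1)
  dist_tss <- ifelse(meta$start <= tss & tss < v_end, 0,
                     pmin(abs(meta$start - tss), abs(v_end - 1 - tss)))
  o <- order(a$p, dist_tss, a$variant)
  idx <- o[1]
  list(variant = a$variant[idx], beta = a$beta[idx], p = a$p[idx],
       distance_to_tss = dist_tss[idx])
}

#' Map cis-eQTLs across a cohort
#'
#' The package's main fitting function: runs the per-gene linear-mixed-model
#' cis scan, permutation adjustment and Storey-q eGene calling over a full
#' cohort, and returns a classed fit object.
#'
#' @param expression genes x samples matrix of TPM values (filtered and
#'   standardized internally via \code{\link{prepare_expression}}), or an
#'   already-processed matrix if \code{prepared = TRUE}.
#' @param dosages a \code{\link{build_dosage_matrix}} result.
#' @param genes data.frame of gene models with \code{id}, \code{chrom},
#'   \code{start}, \code{end}, \code{tss} columns (e.g. from the synthetic
#'   cohort or a GTF via \code{\link{read_gene_models}}).
#' @param kinship samples x samples kinship matrix.
#' @param covariates optional samples x covariates matrix; if \code{NULL},
#'   \code{n_expression_pcs} expression principal components are used.
#' @param mode "joint" (all variant classes) or "svstr" (SVs and STRs only).
#' @param window cis-window half-width in bp.
#' @param n_perm permutations per gene.
#' @param perm_mode "beta" or "empirical" adjustment.
#' @param fdr eGene q-value threshold.
#' @param n_expression_pcs number of expression PCs when no covariates are
#'   given (default 10; 0 for intercept only).
#' @param prepared set TRUE if \code{expression} is already log-standardized.
#' @param seed integer seed controlling the permutation streams.
#' @return object of class \code{cis_eqtl} with elements \code{associations}
#'   (all nominal tests), \code{egenes} (gene-level results), \code{vc}
#'   (per-gene variance components), and the call configuration.
#' @export
map_cis_eqtl <- function(expression, dosages, genes, kinship,
                         covariates = NULL, mode = c("joint", "svstr"),
                         window = 1e6, n_perm = 1000,
                         perm_mode = c("beta", "empirical"), fdr = 0.05,
                         n_expression_pcs = 10, prepared = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  perm_mode <- match.arg(perm_mode)
  stopifnot(inherits(dosages, "dosage_matrix"))
  if (prepared) {
    processed <- as.matrix(expression)
  } else {
    processed <- prepare_expression(expression)$processed
  }
  samples <- colnames(processed)
  if (!identical(samples, dosages$samples) ||
      !identical(samples, rownames(kinship))) {
    stop("sample ids must be identical across expression, dosages and kinship")
  }
  vmeta <- dosages$variants
  if (mode == "svstr") {
    svstr <- !(vmeta$variant_class %in% c("SNV", "indel"))
    vmeta <- vmeta[svstr, , drop = FALSE]
  }
  if (is.null(covariates) && n_expression_pcs > 0) {
    covariates <- expression_pcs(processed, n_expression_pcs)
  }
  C <- build_covariates(covariates, length(samples))
  eig <- eigen(kinship, symmetric = TRUE)
  if (min(eig$values) < -1e-8) stop("kinship matrix is not positive semi-definite")

  assoc_list <- list()
  gene_rows <- list()
  vc_list <- list()
  tested_genes <- intersect(rownames(processed), genes$id)
  for (g in tested_genes) {
    gm <- genes[genes$id == g, ]
    cis_ids <- cis_pairs(gm, vmeta, window = window)
    if (length(cis_ids) == 0) next
    G <- t(dosages$dosages[cis_ids, , drop = FALSE])
    y <- processed[g, ]
    scan <- lmm_scan(y, G, C, kinship, eig = eig)
    adj <- permutation_adjust(scan, G, n_perm = n_perm, mode = perm_mode,
                              rng_state = seed + match(g, tested_genes))
    lead <- pick_lead(scan$associations, vmeta, gm$tss)
    if (is.null(lead)) next
    a <- scan$associations
    a$gene <- g
    assoc_list[[g]] <- a
    vc_list[[g]] <- scan$vc
    gene_rows[[g]] <- data.frame(
      gene = g, p_adjusted = adj$p_adjusted, n_perm = adj$n_perm,
      lead_variant = lead$variant, beta_lead = lead$beta, p_lead = lead$p,
      lead_distance_to_tss = lead$distance_to_tss,
      n_cis_variants = length(cis_ids), stringsAsFactors = FALSE)
  }
  if (length(gene_rows) == 0) stop("no gene could be tested (no cis variants)")
  gene_results <- call_egenes(do.call(rbind, gene_rows), fdr = fdr)
  res <- list(associations = do.call(rbind, assoc_list),
              egenes = gene_results,
              vc = vc_list,
              config = list(mode = mode, window = window, n_perm = n_perm,
                            perm_mode = perm_mode, fdr = fdr, seed = seed,
                            n_samples = length(samples),
                            n_genes_tested = nrow(gene_results)),
              pi0 = attr(gene_results, "pi0"))
  class(res) <- "cis_eqtl"
  res
}

#' @export
print.cis_eqtl <- function(x, ...) {
  cat("cis-eQTL scan (", x$config$mode, " mode)\n", sep = "")
  cat("  samples:", x$config$n_samples,
      " genes tested:", x$config$n_genes_tested, "\n")
  cat("  eGenes at FDR", x$config$fdr, ":", sum(x$egenes$egene), "\n")
  invisible(x)
}

#' @export
summary.cis_eqtl <- function(object, ...) {
  eg <- object$egenes[object$egenes$egene, ]
  out <- list(n_genes = nrow(object$egenes), n_egenes = nrow(eg),
              pi0 = object$pi0, fdr = object$config$fdr,
              lead_beta_range = if (nrow(eg)) range(abs(eg$beta_lead)) else c(NA, NA),
              egenes = eg)
  class(out) <- "summary.cis_eqtl"
  out
}

#' @export
print.summary.cis_eqtl <- function(x, ...) {
  cat("cis-eQTL summary:", x$n_egenes, "eGenes /", x$n_genes,
      "tested genes (q <", x$fdr, ", estimated pi0 =",
      round(x$pi0, 3), ")\n")
  if (x$n_egenes > 0) {
    cat("  |lead beta| range:", paste(round(x$lead_beta_range, 3), collapse = " - "), "\n")
    print(utils::head(x$egenes[, c("gene", "lead_variant", "beta_lead",
                                   "p_adjusted", "q_value")], 10))
  }
  invisible(x)
}

#' @export
coef.cis_eqtl <- function(object, ...) {
  stats::setNames(object$egenes$beta_lead, object$egenes$gene)
}

#' @export
plot.cis_eqtl <- function(x, ...) {
  graphics::hist(x$egenes$p_adjusted, breaks = 20,
                 main = "Permutation-adjusted gene-level p-values",
                 xlab = "adjusted p", col = "grey80", ...)
  graphics::abline(v = x$config$fdr, lty = 2)
  invisible(x)
}
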