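# Variant-gene localization and enrichment analyses: hierarchical 7-category
# classification, distances, variant-length enrichment, length/effect-size
# models, gene-type and constraint analyses.

#' Gene models container
#'
#' @param genes data.frame with \code{id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end} (gene body, 0-based half-open), \code{tss},
#'   and optionally \code{gene_type}, \code{pli}, \code{prec}, \code{pnull},
#'   \code{mean_log_tpm}.
#' @param exons data.frame with \code{gene_id}, \code{start}, \code{end}.
#' @param promoter_upstream,promoter_downstream strand-aware promoter window
#'   around the TSS, in bp.
#' @return object of class \code{gene_models} with a precomputed
#'   \code{promoters} table.
#' @export
gene_models <- function(genes, exons, promoter_upstream = 2000,
                        promoter_downstream = 500) {
  required <- c("id", "chrom", "strand", "start", "end", "tss")
  miss <- setdiff(required, names(genes))
  if (length(miss)) stop("genes is missing columns: ", paste(miss, collapse = ", "))
  bad <- exons$start < genes$start[match(exons$gene_id, genes$id)] - 1 |
    exons$end > genes$end[match(exons$gene_id, genes$id)] + 1
  if (any(bad, na.rm = TRUE)) stop("exons must lie within their gene body")
  pr <- t(mapply(promoter_interval, genes$tss, genes$strand,
                 MoreArgs = list(upstream = promoter_upstream,
                                 downstream = promoter_downstream)))
  promoters <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                          start = pr[, 1], end = pr[, 2],
                          stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, promoters = promoters,
                 promoter_window = c(upstream = promoter_upstream,
                                     downstream = promoter_downstream)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Strand-aware promoter interval
#'
#' Window of \code{upstream} bp upstream and \code{downstream} bp downstream
#' of the TSS in the direction of transcription, 0-based half-open; always
#' contains the TSS.
#'
#' @param tss TSS position (0-based).
#' @param strand "+" or "-".
#' @param upstream,downstream window extents in bp.
#' @return numeric c(start, end).
#' @export
promoter_interval <- function(tss, strand, upstream = 2000, downstream = 500) {
  if (strand == "-") {
    c(tss - downstream + 1, tss + upstream + 1)
  } else {
    c(tss - upstream, tss + downstream)
  }
}

# gap between two 0-based half-open intervals; 0 when they overlap.
# Zero-width intervals (insertion points) are widened to 1 bp.
interval_gap <- function(s1, e1, s2, e2) {
  e1 <- pmax(e1, s1 + 1)
  e2 <- pmax(e2, s2 + 1)
  pmax(0, pmax(s2 - e1, s1 - e2))
}

# strict overlap: the intervals share at least one base pair (adjacent
# intervals have gap 0 but do not overlap)
intervals_overlap <- function(s1, e1, s2, e2) {
  e1 <- pmax(e1, s1 + 1)
  e2 <- pmax(e2, s2 + 1)
  s1 < e2 & s2 < e1
}

#' Hierarchical variant-gene category
#'
#' Assigns exactly one of seven categories to a variant-gene pair, in order
#' of precedence: exonic eGene > promoter eGene > intronic eGene > exonic
#' other > promoter other > intronic other > intergenic. "eGene" features
#' belong to the tested gene, "other" features to any other gene; a variant
#' overlaps a feature if they share at least one base pair. Introns are the
#' gene body minus exons minus promoter.
#'
#' @param variant one-row data.frame (or list) with \code{chrom},
#'   \code{start}, \code{end}.
#' @param gene the tested gene id.
#' @param models a \code{\link{gene_models}} object.
#' @return one of "exonic_egene", "promoter_egene", "intronic_egene",
#'   "exonic_other", "promoter_other", "intronic_other", "intergenic".
#' @export
classify_variant_gene <- function(variant, gene, models) {
  vs <- variant$start; ve <- variant$end
  hit_gene <- function(gids, what) {
    if (what == "exon") {
      f <- models$exons[models$exons$gene_id %in% gids, , drop = FALSE]
    } else if (what == "promoter") {
      f <- models$promoters[models$promoters$gene_id %in% gids, , drop = FALSE]
    } else { # intron: body overlap not explained by exon or promoter
      g <- models$genes[models$genes$id %in% gids, , drop = FALSE]
      return(any(intervals_overlap(vs, ve, g$start, g$end) &
                   vapply(seq_len(nrow(g)), function(i) {
                     intron_overlap(vs, ve, g[i, ], models)
                   }, logical(1))))
    }
    nrow(f) > 0 && any(intervals_overlap(vs, ve, f$start, f$end))
  }
  others <- setdiff(models$genes$id, gene)
  if (hit_gene(gene, "exon")) return("exonic_egene")
  if (hit_gene(gene, "promoter")) return("promoter_egene")
  if (hit_gene(gene, "intron")) return("intronic_egene")
  if (length(others)) {
    if (hit_gene(others, "exon")) return("exonic_other")
    if (hit_gene(others, "promoter")) return("promoter_other")
    if (hit_gene(others, "intron")) return("intronic_other")
  }
  "intergenic"
}

# does [vs, ve) overlap the intronic part of gene g (body minus exons minus
# promoter)?
intron_overlap <- function(vs, ve, g, models) {
  ve <- max(ve, vs + 1)
  ex <- models$exons[models$exons$gene_id == g$id, , drop = FALSE]
  pr <- models$promoters[models$promoters$gene_id == g$id, , drop = FALSE]
  # subtract exon and promoter intervals from the body, then test overlap
  segs <- data.frame(start = g$start, end = g$end)
  cut <- rbind(ex[, c("start", "end")], pr[, c("start", "end")])
  for (i in seq_len(nrow(cut))) {
    new <- list()
    for (j in seq_len(nrow(segs))) {
      s <- segs$start[j]; e <- segs$end[j]
      cs <- max(cut$start[i], s); ce <- min(cut$end[i], e)
      if (cs >= ce) { new[[length(new) + 1]] <- c(s, e); next }
      if (s < cs) new[[length(new) + 1]] <- c(s, cs)
      if (ce < e) new[[length(new) + 1]] <- c(ce, e)
    }
    if (length(new) == 0) return(FALSE)
    segs <- as.data.frame(do.call(rbind, new))
    names(segs) <- c("start", "end")
  }
  any(segs$start < ve & vs < segs$end)
}

#' Classify many variant-gene pairs
#'
#' @param pairs data.frame with \code{variant}, \code{gene} columns.
#' @param variants data.frame of variant metadata (\code{id}, \code{chrom},
#'   \code{start}, \code{end}).
#' @param models a \code{\link{gene_models}} object.
#' @return \code{pairs} with a \code{category} column.
#' @export
classify_pairs <- function(pairs, variants, models) {
  idx <- match(pairs$variant, variants$id)
  pairs$category <- vapply(seq_len(nrow(pairs)), function(i) {
    classify_variant_gene(variants[idx[i], ], pairs$gene[i], models)
  }, character(1))
  pairs
}

#' Distances from a variant to a gene
#'
#' Gap in bp from the variant interval to the gene's TSS (a point) and gene
#' body (an interval); 0 when overlapping.
#'
#' @param variant one-row data.frame/list with \code{start}, \code{end}.
#' @param gene one-row data.frame/list with \code{start}, \code{end},
#'   \code{tss}.
#' @return list with \code{to_tss} and \code{to_body} in bp.
#' @export
distance_to_gene <- function(variant, gene) {
  list(to_tss = interval_gap(variant$start, variant$end, gene$tss, gene$tss + 1),
       to_body = interval_gap(variant$start, variant$end, gene$start, gene$end))
}

#' Variant-length enrichment among eVariants
#'
#' For each variant class and length threshold, compares the proportion of
#' eVariants (and separately lead eVariants) among variants longer than the
#' threshold to the proportion among shorter variants (Fisher's exact test,
#' sample odds ratio), with Benjamini-Hochberg adjustment across thresholds
#' within each class and outcome.
#'
#' @param variants data.frame with \code{variant_class}, \code{length},
#'   logical \code{is_evariant} and \code{is_lead} columns.
#' @param thresholds numeric vector of length thresholds in bp.
#' @param classes classes to analyse (default: the length-polymorphic ones).
#' @return data.frame: class, threshold, outcome, the 2x2 cells, odds_ratio,
#'   p, q, and a \code{testable} flag (FALSE when a stratum is empty).
#' @export
length_enrichment <- function(variants,
                              thresholds = c(100, 1000, 1e4, 5e4, 1e5),
                              classes = c("DEL", "DUP", "mCNV", "STR")) {
  rows <- list()
  for (cl in intersect(classes, unique(variants$variant_class))) {
    v <- variants[variants$variant_class == cl, ]
    for (outcome in c("is_evariant", "is_lead")) {
      for (th in thresholds) {
        longer <- v$length > th
        if (!any(longer) || all(longer)) {
          rows[[length(rows) + 1]] <- data.frame(
            class = cl, threshold = th, outcome = outcome,
            a = NA, b = NA, c = NA, d = NA, odds_ratio = NA_real_,
            p = NA_real_, testable = FALSE, stringsAsFactors = FALSE)
          next
        }
        tab <- matrix(c(sum(v[[outcome]][longer]), sum(!v[[outcome]][longer]),
                        sum(v[[outcome]][!longer]), sum(!v[[outcome]][!longer])),
                      nrow = 2, byrow = TRUE)
        ft <- fisher_exact(tab)
        rows[[length(rows) + 1]] <- data.frame(
          class = cl, threshold = th, outcome = outcome,
          a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
          odds_ratio = ft$odds_ratio, p = ft$p, testable = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (cl in unique(out$class)) {
    for (outcome in unique(out$outcome)) {
      sel <- out$class == cl & out$outcome == outcome & out$testable
      if (any(sel)) out$q[sel] <- adjust_pvalues(out$p[sel], "bh")
    }
  }
  out
}

#' Variant length vs eQTL effect size
#'
#' Regresses the absolute effect size of lead eQTL associations on
#' log10(variant length), with non-mode allele frequency and distance to
#' TSS as covariates. The default model is linear with a t-test on the
#' length term; a logistic alternative (quasi-binomial on |beta| clipped to
#' (0, 1)) is available.
#'
#' @param eqtls data.frame with \code{abs_beta}, \code{length}, \code{nmaf},
#'   \code{distance_to_tss} columns; at least 10 rows.
#' @param model "linear" (default) or "logistic".
#' @return list with \code{slope}, \code{se}, \code{p} for the length term
#'   and the full \code{coefficients} table.
#' @export
length_effect_model <- function(eqtls, model = c("linear", "logistic")) {
  model <- match.arg(model)
  if (nrow(eqtls) < 10) stop("need at least 10 observations")
  design <- data.frame(log10_length = log10(pmax(eqtls$length, 1)),
                       nmaf = eqtls$nmaf,
                       distance_to_tss = eqtls$distance_to_tss)
  response <- if (model == "linear") eqtls$abs_beta else
    pmin(pmax(eqtls$abs_beta, 1e-6), 1 - 1e-6)
  fit <- glm_fit(response, design, family = if (model == "linear") "linear" else "logistic")
  co <- fit$coefficients
  row <- co[co$term == "log10_length", ]
  list(slope = row$estimate, se = row$se, p = row$p, coefficients = co,
       model = model)
}

#' Length-effect models across classes and exonic strata
#'
#' Fits \code{\link{length_effect_model}} separately per variant class and
#' exonic/non-exonic stratum and Bonferroni-adjusts the length-term
#' p-values across all fitted strata.
#'
#' @param eqtls data.frame as for \code{\link{length_effect_model}} plus
#'   \code{variant_class} and logical \code{exonic} columns.
#' @param classes classes to analyse.
#' @param model passed to \code{\link{length_effect_model}}.
#' @return data.frame: class, stratum, n, slope, se, p, p_bonferroni.
#' @export
length_effect_models <- function(eqtls, classes = c("DEL", "DUP", "mCNV", "STR"),
                                 model = "linear") {
  rows <- list()
  for (cl in intersect(classes, unique(eqtls$variant_class))) {
    for (ex in c(FALSE, TRUE)) {
      sub <- eqtls[eqtls$variant_class == cl & eqtls$exonic == ex, ]
      if (nrow(sub) < 10) next
      m <- tryCatch(length_effect_model(sub, model), error = function(e) NULL)
      if (is.null(m)) next
      rows[[length(rows) + 1]] <- data.frame(
        class = cl, stratum = if (ex) "exonic" else "non_exonic",
        n = nrow(sub), slope = m$slope, se = m$se, p = m$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out$p_bonferroni <- adjust_pvalues(out$p, "bonferroni")
  out
}

#' eGene gene-type and constraint analyses
#'
#' Three analyses of eGene properties: (a) per variant class x gene type,
#' Fisher's exact test of the gene-type composition of that class's eGenes
#' against eGenes of all other classes (BH-adjusted); (b) per class,
#' Fisher's exact test of the proportion of eGenes with a high (> 0.9)
#' constraint score (pLI, pRec, pNull) against tested non-eGenes
#' (Bonferroni-adjusted); (c) a logistic (quasi-binomial) model predicting
#' pLI from the eGene's absolute lead effect size with mean log TPM as a
#' covariate, reporting the effect-size term's t-test p.
#'
#' @param egenes data.frame of eGenes: \code{gene}, \code{lead_class},
#'   \code{abs_beta}, \code{gene_type}, \code{pli}, \code{prec},
#'   \code{pnull}, \code{mean_log_tpm}.
#' @param non_egenes data.frame of tested non-eGenes with \code{gene_type},
#'   \code{pli}, \code{prec}, \code{pnull}.
#' @param high_score constraint-score threshold (default 0.9).
#' @return list with \code{gene_type} (data.frame), \code{constraint}
#'   (data.frame), \code{pli_model} (coefficient row for abs_beta), and
#'   \code{n_excluded} genes without constraint scores.
#' @export
egene_property_tests <- function(egenes, non_egenes, high_score = 0.9) {
  n_excluded <- sum(is.na(egenes$pli)) + sum(is.na(non_egenes$pli))
  egenes_c <- egenes[!is.na(egenes$pli), ]
  non_c <- non_egenes[!is.na(non_egenes$pli), ]

  # (a) gene-type composition per lead class vs other classes
  gt_rows <- list()
  for (cl in unique(egenes$lead_class)) {
    in_cl <- egenes$lead_class == cl
    for (ty in unique(egenes$gene_type)) {
      tab <- matrix(c(sum(egenes$gene_type[in_cl] == ty),
                      sum(egenes$gene_type[in_cl] != ty),
                      sum(egenes$gene_type[!in_cl] == ty),
                      sum(egenes$gene_type[!in_cl] != ty)), 2, byrow = TRUE)
      ft <- fisher_exact(tab)
      gt_rows[[length(gt_rows) + 1]] <- data.frame(
        class = cl, gene_type = ty, odds_ratio = ft$odds_ratio, p = ft$p,
        stringsAsFactors = FALSE)
    }
  }
  gene_type <- do.call(rbind, gt_rows)
  gene_type$q <- adjust_pvalues(gene_type$p, "bh")

  # (b) high-constraint proportion per class vs non-eGenes
  cons_rows <- list()
  for (score in c("pli", "prec", "pnull")) {
    for (cl in unique(egenes_c$lead_class)) {
      e <- egenes_c[egenes_c$lead_class == cl, ]
      tab <- matrix(c(sum(e[[score]] > high_score),
                      sum(e[[score]] <= high_score),
                      sum(non_c[[score]] > high_score),
                      sum(non_c[[score]] <= high_score)), 2, byrow = TRUE)
      ft <- fisher_exact(tab)
      cons_rows[[length(cons_rows) + 1]] <- data.frame(
        score = score, class = cl, n_egenes = nrow(e),
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  constraint <- do.call(rbind, cons_rows)
  constraint$p_bonferroni <- adjust_pvalues(constraint$p, "bonferroni")

  # (c) pLI ~ |beta| + mean log TPM
  pli_model <- NULL
  if (nrow(egenes_c) >= 10) {
    fit <- glm_fit(pmin(pmax(egenes_c$pli, 1e-6), 1 - 1e-6),
                   data.frame(abs_beta = egenes_c$abs_beta,
                              mean_log_tpm = egenes_c$mean_log_tpm),
                   family = "logistic")
    pli_model <- fit$coefficients[fit$coefficients$term == "abs_beta", ]
  }
  list(gene_type = gene_type, constraint = constraint, pli_model = pli_model,
       n_excluded = n_excluded)
}
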