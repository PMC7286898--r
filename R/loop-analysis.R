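# Chromatin-loop analyses: distal variant-gene pair filters, anchor
# intersection, distance models and multi-gene loop tests.

#' Anchor intersection within slop
#'
#' A variant intersects a loop anchor when the gap between the variant
#' interval and the anchor interval is at most \code{slop} bp (default
#' 10 kb), overlap included.
#'
#' @param variant one-row data.frame/list with \code{start}, \code{end}.
#' @param anchor_start,anchor_end anchor interval (0-based half-open).
#' @param slop maximum gap in bp.
#' @return logical.
#' @export
anchor_intersect <- function(variant, anchor_start, anchor_end, slop = 10000) {
  interval_gap(variant$start, variant$end, anchor_start, anchor_end) <= slop
}

#' Distal variant-gene pair filter
#'
#' Labels a variant-gene pair against the gene's chromatin loops. The pair
#' is a distal pair when, for the nearest qualifying loop (smallest distance
#' to the distal anchor), all criteria hold: (1) the variant is closer to
#' the distal anchor than to the promoter anchor (midpoint distances);
#' (2) it is at least \code{min_promoter_gap} bp from the gene's promoter;
#' (3) it is at most \code{max_anchor_gap} bp from the distal anchor;
#' (4) it does not overlap an exon of the tested gene (toggleable).
#'
#' @param variant one-row variant metadata (\code{start}, \code{end}).
#' @param gene the tested gene id.
#' @param loops loop data.frame (\code{gene}, \code{p_start}, \code{p_end},
#'   \code{d_start}, \code{d_end}).
#' @param models a \code{\link{gene_models}} object.
#' @param min_promoter_gap minimum distance from the promoter (bp).
#' @param max_anchor_gap maximum distance from the distal anchor (bp).
#' @param exclude_exon_overlap apply criterion (4) (default TRUE).
#' @param promoter_gap_from "promoter" (default) or "body": the feature the
#'   minimum-gap criterion is measured from.
#' @return one-row data.frame: \code{variant} fields echoed, \code{gene},
#'   \code{is_distal_pair}, \code{inside_loop},
#'   \code{distance_to_distal_anchor}, \code{distance_to_promoter_anchor},
#'   \code{anchor_overlap} (within 10 kb slop), \code{reason} for failures.
#' @export
distal_pair_filter <- function(variant, gene, loops, models,
                               min_promoter_gap = 50000,
                               max_anchor_gap = 200000,
                               exclude_exon_overlap = TRUE,
                               promoter_gap_from = c("promoter", "body")) {
  promoter_gap_from <- match.arg(promoter_gap_from)
  gl <- loops[loops$gene == gene, , drop = FALSE]
  out <- data.frame(variant = variant$id %||% NA_character_, gene = gene,
                    is_distal_pair = FALSE, inside_loop = NA,
                    distance_to_distal_anchor = NA_real_,
                    distance_to_promoter_anchor = NA_real_,
                    anchor_overlap = NA, reason = "",
                    stringsAsFactors = FALSE)
  if (nrow(gl) == 0) { out$reason <- "no_loop"; return(out) }
  d_dist <- interval_gap(variant$start, variant$end, gl$d_start, gl$d_end)
  best <- which.min(d_dist)
  loop <- gl[best, ]
  v_mid <- (variant$start + max(variant$end, variant$start + 1)) / 2
  d_mid <- (loop$d_start + loop$d_end) / 2
  p_mid <- (loop$p_start + loop$p_end) / 2
  out$distance_to_distal_anchor <- d_dist[best]
  out$distance_to_promoter_anchor <-
    interval_gap(variant$start, variant$end, loop$p_start, loop$p_end)
  out$inside_loop <- v_mid > min(p_mid, d_mid) & v_mid < max(p_mid, d_mid)
  out$anchor_overlap <- d_dist[best] <= 10000
  g <- models$genes[models$genes$id == gene, ]
  if (promoter_gap_from == "promoter") {
    pr <- models$promoters[models$promoters$gene_id == gene, ]
    prom_gap <- interval_gap(variant$start, variant$end, pr$start, pr$end)
  } else {
    prom_gap <- interval_gap(variant$start, variant$end, g$start, g$end)
  }
  if (abs(v_mid - d_mid) >= abs(v_mid - p_mid)) {
    out$reason <- "closer_to_promoter_anchor"
  } else if (prom_gap < min_promoter_gap) {
    out$reason <- "promoter_gap"
  } else if (d_dist[best] > max_anchor_gap) {
    out$reason <- "anchor_gap"
  } else if (exclude_exon_overlap && {
    ex <- models$exons[models$exons$gene_id == gene, ]
    nrow(ex) > 0 && any(intervals_overlap(variant$start, variant$end,
                                          ex$start, ex$end))
  }) {
    out$reason <- "exon_overlap"
  } else {
    out$is_distal_pair <- TRUE
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Label all variant-gene pairs against loops
#'
#' Applies \code{\link{distal_pair_filter}} to every supplied pair and adds
#' the number of genes each variant is loop-connected to (variants within
#' the 10 kb anchor slop of a loop's distal anchor count as connected to
#' that loop's gene).
#'
#' @param pairs data.frame with \code{variant}, \code{gene}.
#' @param variants variant metadata data.frame (\code{id}, \code{start},
#'   \code{end}).
#' @param loops loop data.frame.
#' @param models a \code{\link{gene_models}} object.
#' @param ... passed to \code{\link{distal_pair_filter}}.
#' @return data.frame of labels, one row per pair, plus
#'   \code{n_looped_genes} per variant.
#' @export
label_distal_pairs <- function(pairs, variants, loops, models, ...) {
  idx <- match(pairs$variant, variants$id)
  labels <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    distal_pair_filter(variants[idx[i], ], pairs$gene[i], loops, models, ...)
  }))
  labels$variant <- pairs$variant
  # loop connectivity per variant: genes whose distal anchor is within slop
  n_looped <- vapply(seq_len(nrow(pairs)), function(i) {
    v <- variants[idx[i], ]
    hit <- interval_gap(v$start, v$end, loops$d_start, loops$d_end) <= 10000
    length(unique(loops$gene[hit]))
  }, integer(1))
  labels$n_looped_genes <- n_looped
  labels
}

#' Anchor-distance model for eQTL likelihood
#'
#' On distal variant-gene pairs at least \code{min_gene_gap} bp from the
#' gene body and within 200 kb of the distal anchor, fits a logistic model
#' of eQTL status on distance to the distal anchor with distance to the
#' gene body and non-mode allele frequency as covariates, separately for
#' pairs inside and outside the loop; plus a Fisher's exact test comparing
#' eVariant proportions inside vs outside within 100 kb of the anchor.
#'
#' @param pairs data.frame with \code{is_eqtl} (logical),
#'   \code{distance_to_distal_anchor}, \code{distance_to_gene_body},
#'   \code{nmaf}, \code{inside_loop}.
#' @param min_gene_gap minimum distance from the gene body in bp.
#' @return list with \code{inside}, \code{outside} (coefficient tables or
#'   NULL), \code{combined} (single fit with an inside/outside term), and
#'   \code{inside_vs_outside} enrichment (\code{stat_result}).
#' @export
loop_distance_model <- function(pairs, min_gene_gap = 100000) {
  sub <- pairs[pairs$distance_to_gene_body >= min_gene_gap &
                 pairs$distance_to_distal_anchor <= 200000, ]
  if (nrow(sub) < 10) stop("too few qualifying pairs")
  if (stats::sd(sub$distance_to_distal_anchor) == 0) {
    stop("degenerate predictor: all pairs at the same anchor distance")
  }
  fit_side <- function(d) {
    if (nrow(d) < 10 || length(unique(d$is_eqtl)) < 2) return(NULL)
    glm_fit(as.numeric(d$is_eqtl),
            data.frame(distance_to_anchor = d$distance_to_distal_anchor / 1e5,
                       distance_to_body = d$distance_to_gene_body / 1e5,
                       nmaf = d$nmaf),
            family = "logistic")$coefficients
  }
  combined <- glm_fit(as.numeric(sub$is_eqtl),
                      data.frame(distance_to_anchor = sub$distance_to_distal_anchor / 1e5,
                                 distance_to_body = sub$distance_to_gene_body / 1e5,
                                 nmaf = sub$nmaf,
                                 inside = as.numeric(sub$inside_loop)),
                      family = "logistic")$coefficients
  near <- sub[sub$distance_to_distal_anchor <= 100000, ]
  tab <- matrix(c(sum(near$is_eqtl[near$inside_loop]),
                  sum(!near$is_eqtl[near$inside_loop]),
                  sum(near$is_eqtl[!near$inside_loop]),
                  sum(!near$is_eqtl[!near$inside_loop])), 2, byrow = TRUE)
  list(inside = fit_side(sub[sub$inside_loop, ]),
       outside = fit_side(sub[!sub$inside_loop, ]),
       combined = combined,
       inside_vs_outside = fisher_exact(tab),
       n_pairs = nrow(sub))
}

#' Multi-gene loop tests
#'
#' (a) Per loop-connectivity level k, Fisher's exact test comparing the
#' eVariant (and lead-eVariant) proportion among variants loop-connected to
#' k genes against variants connected to none. (b) A model of each
#' variant's eGene count on its tested-gene count with a loop/non-loop
#' stratum term: each variant contributes one observation per stratum
#' (genes connected by loops vs not), and the stratum term's t-test p is
#' reported.
#'
#' @param variant_stats data.frame with one row per tested variant:
#'   \code{n_looped_genes}, \code{n_genes_tested}, \code{n_egenes},
#'   \code{n_looped_egenes}, \code{is_evariant}, \code{is_lead}.
#' @return list with \code{per_k} (data.frame of enrichments) and
#'   \code{stratum_model} (coefficient table; the \code{looped} term is the
#'   stratum effect).
#' @export
multigene_loop_tests <- function(variant_stats) {
  base <- variant_stats[variant_stats$n_looped_genes == 0, ]
  per_k <- list()
  for (k in sort(unique(variant_stats$n_looped_genes))) {
    if (k == 0) next
    vk <- variant_stats[variant_stats$n_looped_genes == k, ]
    if (nrow(vk) == 0 || nrow(base) == 0) next
    for (outcome in c("is_evariant", "is_lead")) {
      tab <- matrix(c(sum(vk[[outcome]]), sum(!vk[[outcome]]),
                      sum(base[[outcome]]), sum(!base[[outcome]])), 2,
                    byrow = TRUE)
      ft <- fisher_exact(tab)
      per_k[[length(per_k) + 1]] <- data.frame(
        k = k, outcome = outcome, n = nrow(vk),
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  # stratified model: one observation per variant per stratum
  long <- rbind(
    data.frame(n_egenes = variant_stats$n_looped_egenes,
               n_tested = variant_stats$n_looped_genes, looped = 1),
    data.frame(n_egenes = variant_stats$n_egenes - variant_stats$n_looped_egenes,
               n_tested = variant_stats$n_genes_tested - variant_stats$n_looped_genes,
               looped = 0))
  long <- long[long$n_tested >= 0, ]
  model <- NULL
  if (nrow(long) >= 10 && stats::sd(long$looped) > 0 &&
      stats::sd(long$n_tested) > 0) {
    model <- glm_fit(long$n_egenes,
                     data.frame(n_tested = long$n_tested, looped = long$looped),
                     family = "linear")$coefficients
  }
  list(per_k = if (length(per_k)) do.call(rbind, per_k) else NULL,
       stratum_model = model)
}
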