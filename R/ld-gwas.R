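# LD tagging of SVs/STRs against a panel of nearby SNVs and GWAS trait
# linkage.

#' Squared Pearson correlation between dosage vectors
#'
#' LD between two variants computed as the squared Pearson correlation of
#' their dosage vectors, which extends naturally to multiallelic and
#' continuous encodings. Returns \code{NA} when either vector is constant.
#'
#' @param dosage_a,dosage_b numeric vectors of equal length (>= 3 samples).
#' @return r-squared in [0, 1], or \code{NA} for a degenerate input.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) stop("dosage vectors differ in length")
  if (length(dosage_a) < 3) stop("need at least 3 samples")
  if (stats::sd(dosage_a) == 0 || stats::sd(dosage_b) == 0) return(NA_real_)
  min(stats::cor(dosage_a, dosage_b)^2, 1)
}

#' Tag an SV/STR against the panel
#'
#' Considers panel SNVs whose position lies within \code{window} bp of the
#' variant's interval boundaries (closed window), computes dosage r2 against
#' each, and records the best tag overall and the best among trait-tested
#' SNVs. The variant is tagged when the best in-panel r2 exceeds
#' \code{r2_threshold}; linked traits are those with p below \code{gwas_p}
#' on any SNV in strong LD (r2 > \code{r2_threshold}) with the variant.
#'
#' @param variant one-row variant metadata (\code{id}, \code{start},
#'   \code{end}).
#' @param dosage the variant's per-sample dosage vector.
#' @param panel list with \code{snvs} (data.frame: id, pos), \code{dosages}
#'   (tags x samples matrix), \code{traits} (data.frame: snv, trait, p).
#' @param window boundary-anchored window in bp (default 50 kb).
#' @param r2_threshold strong-LD threshold (default 0.8, strict).
#' @param gwas_p genome-wide significance threshold (default 5e-8).
#' @return one-row data.frame: variant, best_tag, r2, best_tag_in_panel,
#'   r2_in_panel, tagged, n_linked_traits, linked_traits
#'   (comma-separated), reason ("no_snv" when the window is empty).
#' @export
tag_variants <- function(variant, dosage, panel, window = 50000,
                         r2_threshold = 0.8, gwas_p = 5e-8) {
  v_end <- max(variant$end, variant$start + 1)
  lo <- variant$start - window
  hi <- (v_end - 1) + window
  in_win <- panel$snvs$pos >= lo & panel$snvs$pos <= hi
  out <- data.frame(variant = variant$id, best_tag = NA_character_,
                    r2 = NA_real_, best_tag_in_panel = NA_character_,
                    r2_in_panel = NA_real_, tagged = FALSE,
                    n_linked_traits = 0L, linked_traits = "",
                    reason = "", stringsAsFactors = FALSE)
  if (!any(in_win)) { out$reason <- "no_snv"; return(out) }
  ids <- panel$snvs$id[in_win]
  r2s <- vapply(ids, function(s) {
    r <- ld_r2(dosage, panel$dosages[s, ])
    if (is.na(r)) -1 else r
  }, 0)
  usable <- r2s >= 0
  if (!any(usable)) { out$reason <- "degenerate"; return(out) }
  ids <- ids[usable]; r2s <- r2s[usable]
  best <- which.max(r2s)
  out$best_tag <- ids[best]
  out$r2 <- r2s[best]
  in_panel <- ids %in% panel$traits$snv
  if (any(in_panel)) {
    bp <- which.max(ifelse(in_panel, r2s, -1))
    out$best_tag_in_panel <- ids[bp]
    out$r2_in_panel <- r2s[bp]
    out$tagged <- r2s[bp] > r2_threshold
    strong <- ids[in_panel & r2s > r2_threshold]
    if (length(strong)) {
      tt <- panel$traits[panel$traits$snv %in% strong & panel$traits$p < gwas_p, ]
      traits <- sort(unique(tt$trait))
      out$n_linked_traits <- length(traits)
      out$linked_traits <- paste(traits, collapse = ",")
    }
  }
  out
}

#' Tag every SV/STR in a dosage matrix
#'
#' @param dosages a \code{\link{build_dosage_matrix}} result.
#' @param panel GWAS panel (see \code{\link{tag_variants}}).
#' @param classes variant classes to tag (default all SV/STR classes).
#' @param ... passed to \code{\link{tag_variants}}.
#' @return data.frame with one row per tagged-candidate variant plus its
#'   \code{variant_class}.
#' @export
ld_tag_scan <- function(dosages, panel,
                        classes = setdiff(VARIANT_CLASSES, c("SNV", "indel")),
                        ...) {
  vmeta <- dosages$variants[dosages$variants$variant_class %in% classes, ]
  out <- do.call(rbind, lapply(seq_len(nrow(vmeta)), function(i) {
    tag_variants(vmeta[i, ], dosages$dosages[vmeta$id[i], ], panel, ...)
  }))
  out$variant_class <- vmeta$variant_class
  out
}

#' eQTL/GWAS enrichment tests
#'
#' Per variant class: (1) Fisher's exact test of the tagged proportion among
#' lead eVariants vs non-lead variants; (2) the same for the trait-linked
#' proportion; (3) a logistic model of trait linkage on the number of
#' associated eGenes, with Wald z-test p-values Benjamini-Hochberg adjusted
#' across classes. Classes with fewer than 2 lead eVariants are skipped.
#'
#' @param ld data.frame from \code{\link{ld_tag_scan}} augmented with
#'   logical \code{is_lead} and integer \code{n_egenes} columns.
#' @return list with \code{tagged} and \code{trait_linked} enrichment
#'   data.frames and \code{trait_model} (per-class logistic coefficients
#'   with \code{q}).
#' @export
gwas_enrichment_tests <- function(ld) {
  ld$trait_linked <- ld$n_linked_traits > 0
  tag_rows <- trait_rows <- model_rows <- list()
  for (cl in unique(ld$variant_class)) {
    d <- ld[ld$variant_class == cl, ]
    if (sum(d$is_lead) < 2) next
    for (what in c("tagged", "trait_linked")) {
      tab <- matrix(c(sum(d[[what]][d$is_lead]), sum(!d[[what]][d$is_lead]),
                      sum(d[[what]][!d$is_lead]), sum(!d[[what]][!d$is_lead])),
                    2, byrow = TRUE)
      ft <- fisher_exact(tab)
      row <- data.frame(class = cl, odds_ratio = ft$odds_ratio, p = ft$p,
                        n_lead = sum(d$is_lead), stringsAsFactors = FALSE)
      if (what == "tagged") tag_rows[[length(tag_rows) + 1]] <- row
      else trait_rows[[length(trait_rows) + 1]] <- row
    }
    if (length(unique(d$trait_linked)) == 2 && stats::sd(d$n_egenes) > 0) {
      fit <- glm_fit(as.numeric(d$trait_linked),
                     data.frame(n_egenes = d$n_egenes), family = "logistic")
      co <- fit$coefficients[fit$coefficients$term == "n_egenes", ]
      model_rows[[length(model_rows) + 1]] <-
        cbind(data.frame(class = cl, stringsAsFactors = FALSE), co)
    }
  }
  bindr <- function(l) if (length(l)) do.call(rbind, l) else NULL
  trait_model <- bindr(model_rows)
  if (!is.null(trait_model)) trait_model$q <- adjust_pvalues(trait_model$p, "bh")
  list(tagged = bindr(tag_rows), trait_linked = bindr(trait_rows),
       trait_model = trait_model)
}
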