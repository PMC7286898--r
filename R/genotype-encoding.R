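# Caller-style genotype fields -> analysis-ready dosages on a 0-2 scale.
#
# Four raw encodings are supported, mirroring the callers that produce each
# variant class:
#   str_gb        STR base-pair length differences from the reference, one
#                 pair of per-allele diffs per sample ("a|b")
#   copy_number   integer diploid copy number
#   allele_balance fraction in [0,1] of read evidence for the variant allele
#   biallelic_gt  0/0, 0/1, 1/1 genotypes (MEIs, SNVs, indels)
# Missing entries are "." at any position.

VARIANT_CLASSES <- c("SNV", "indel", "DEL", "DUP", "mCNV", "INV", "BND",
                     "rMEI", "ALU", "LINE1", "SVA", "STR")
ENCODING_KINDS <- c("str_gb", "copy_number", "allele_balance", "biallelic_gt")

#' Construct a set of variant records
#'
#' Bundles per-variant metadata with the raw per-sample genotype fields into
#' the container the encoding and annotation steps consume. Coordinates are
#' 0-based half-open.
#'
#' @param info data.frame with columns \code{id}, \code{variant_class},
#'   \code{chrom}, \code{start}, \code{end}, \code{length}, \code{encoding},
#'   and optionally \code{cluster_id}.
#' @param raw character matrix (variants x samples) of raw genotype fields;
#'   rownames must match \code{info$id}.
#' @return an object of class \code{variant_records}.
#' @export
variant_records <- function(info, raw) {
  required <- c("id", "variant_class", "chrom", "start", "end", "length", "encoding")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols)) {
    stop("info is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(info$cluster_id)) info$cluster_id <- NA_character_
  if (!all(info$variant_class %in% VARIANT_CLASSES)) {
    stop("unknown variant_class: ",
         paste(setdiff(info$variant_class, VARIANT_CLASSES), collapse = ", "))
  }
  if (!all(info$encoding %in% ENCODING_KINDS)) {
    stop("unknown encoding: ",
         paste(setdiff(info$encoding, ENCODING_KINDS), collapse = ", "))
  }
  bad <- info$start > info$end
  if (any(bad)) stop("start > end for: ", paste(info$id[bad], collapse = ", "))
  raw <- as.matrix(raw)
  if (nrow(raw) != nrow(info) || !identical(rownames(raw), as.character(info$id))) {
    stop("raw genotype matrix rows must match info$id")
  }
  structure(list(info = info, raw = raw, samples = colnames(raw)),
            class = "variant_records")
}

#' @export
print.variant_records <- function(x, ...) {
  cat("variant_records:", nrow(x$info), "variants x", length(x$samples), "samples\n")
  print(table(x$info$variant_class))
  invisible(x)
}

is_missing_field <- function(field) {
  is.na(field) | field == "." | field == "./." | field == ".|."
}

#' Convert one variant's raw genotype fields to raw dosages
#'
#' Per-sample conversion before rank scaling: STR fields become the sum of
#' the two per-allele base-pair differences; copy-number fields the integer
#' diploid copy number; allele-balance fields the fraction itself; biallelic
#' genotypes 0/1/2 alternate-allele counts. Missing entries stay missing
#' (\code{NA}).
#'
#' @param raw character vector of per-sample raw fields for one variant.
#' @param encoding one of \code{str_gb}, \code{copy_number},
#'   \code{allele_balance}, \code{biallelic_gt}.
#' @return numeric vector of raw dosages with \code{NA} for missing calls.
#' @examples
#' raw_to_dosage(c("-2|3", "0|0", "."), "str_gb")
#' @export
raw_to_dosage <- function(raw, encoding = ENCODING_KINDS) {
  encoding <- match.arg(encoding)
  out <- rep(NA_real_, length(raw))
  keep <- !is_missing_field(raw)
  if (!any(keep)) return(out)
  val <- raw[keep]
  parsed <- switch(encoding,
    str_gb = {
      parts <- strsplit(val, "|", fixed = TRUE)
      ok <- lengths(parts) == 2L
      if (!all(ok)) {
        stop("malformed GB field at sample index ",
             paste(which(keep)[!ok], collapse = ", "))
      }
      nums <- suppressWarnings(vapply(parts, function(p) sum(as.numeric(p)), 0))
      if (anyNA(nums)) {
        stop("malformed GB field at sample index ",
             paste(which(keep)[is.na(nums)], collapse = ", "))
      }
      nums
    },
    copy_number = {
      nums <- suppressWarnings(as.numeric(val))
      if (anyNA(nums) || any(nums != round(nums)) || any(nums < 0)) {
        stop("malformed CN field at sample index ",
             paste(which(keep)[is.na(nums) | nums != round(nums) | nums < 0],
                   collapse = ", "))
      }
      nums
    },
    allele_balance = {
      nums <- suppressWarnings(as.numeric(val))
      if (anyNA(nums) || any(nums < 0 | nums > 1)) {
        stop("malformed AB field at sample index ",
             paste(which(keep)[is.na(nums) | nums < 0 | nums > 1], collapse = ", "))
      }
      nums
    },
    biallelic_gt = {
      gt <- gsub("|", "/", val, fixed = TRUE)
      counts <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)[gt]
      if (anyNA(counts)) {
        stop("malformed GT field at sample index ",
             paste(which(keep)[is.na(counts)], collapse = ", "))
      }
      unname(counts)
    })
  out[keep] <- parsed
  out
}

#' Rank-normalize raw dosages to a 0-2 scale
#'
#' Replaces non-missing values by their average-tie ranks mapped affinely by
#' \code{(rank - 1) / (n - 1) * 2} over the n non-missing calls, so rank 1
#' maps to 0 and rank n to 2. Missing entries are left untouched (imputation
#' happens after scaling, on the analysis scale). Applied to every encoding
#' except \code{biallelic_gt}, which is already on a 0-2 scale.
#'
#' @param x numeric vector with possible \code{NA}s; needs at least two
#'   distinct non-missing values.
#' @return numeric vector in [0, 2] with the original \code{NA} pattern.
#' @examples
#' rank_scale_02(c(5, 1, 3))
#' @export
rank_scale_02 <- function(x) {
  keep <- !is.na(x)
  v <- x[keep]
  if (length(unique(v)) < 2L) {
    stop("degenerate genotype vector: fewer than 2 distinct non-missing values")
  }
  r <- rank(v)
  x[keep] <- (r - 1) / (length(v) - 1) * 2
  x
}

#' Non-mode allele frequency
#'
#' Fraction of calls that differ from the most common call — the multiallelic
#' analogue of minor allele frequency. For allele-resolved encodings
#' (\code{str_gb}, \code{biallelic_gt}) the count is over individual allele
#' calls (two per sample); for \code{copy_number} and \code{allele_balance}
#' it is over sample-level calls. Ties for the mode are broken toward the
#' reference-like value (bp diff 0, CN 2, AB 0, allele 0).
#'
#' @param raw character vector of per-sample raw fields for one variant.
#' @param encoding the variant's raw encoding.
#' @return frequency in [0, 1).
#' @examples
#' non_mode_allele_freq(c("0|0", "0|2", "2|-1", "0|0", "0|0"), "str_gb")
#' @export
non_mode_allele_freq <- function(raw, encoding = ENCODING_KINDS) {
  encoding <- match.arg(encoding)
  keep <- !is_missing_field(raw)
  if (!any(keep)) stop("all calls missing: non-mode allele frequency undefined")
  val <- raw[keep]
  if (encoding == "str_gb") {
    alleles <- as.numeric(unlist(strsplit(val, "|", fixed = TRUE)))
    non_mode_fraction(alleles, ref_like = 0)
  } else if (encoding == "biallelic_gt") {
    gt <- gsub("|", "/", val, fixed = TRUE)
    alleles <- as.numeric(unlist(strsplit(gt, "/", fixed = TRUE)))
    non_mode_fraction(alleles, ref_like = 0)
  } else if (encoding == "copy_number") {
    non_mode_fraction(as.numeric(val), ref_like = 2)
  } else {
    non_mode_fraction(as.numeric(val), ref_like = 0)
  }
}

non_mode_fraction <- function(calls, ref_like) {
  counts <- table(calls)
  vals <- as.numeric(names(counts))
  top <- which(counts == max(counts))
  # tie-break toward the reference-like value, then the nearest to it
  mode_val <- vals[top][order(abs(vals[top] - ref_like), vals[top])][1]
  mean(calls != mode_val)
}

#' Build a filtered, imputed dosage matrix
#'
#' Applies the variant-inclusion filters and encoding pipeline: variants must
#' have non-mode allele frequency (SVs/STRs) or minor allele frequency
#' (SNVs/indels) of at least 5%, and STRs additionally a 99% call rate.
#' Surviving variants are converted to raw dosages, rank-scaled to [0, 2]
#' (biallelic genotypes pass through as 0/1/2), and missing entries are
#' imputed with the mean dosage among non-missing samples.
#'
#' @param records a \code{\link{variant_records}} object.
#' @param nmaf_min minimum non-mode allele frequency (SV/STR classes).
#' @param maf_min minimum minor allele frequency (SNV/indel).
#' @param str_call_rate_min minimum pre-imputation call rate for STRs.
#' @return an object of class \code{dosage_matrix}: list with \code{dosages}
#'   (variants x samples, no missing values, all in [0, 2]), \code{variants}
#'   (metadata incl. \code{nmaf}, \code{call_rate}), \code{samples}, and
#'   \code{dropped} (data.frame of id + reason for excluded variants).
#' @export
build_dosage_matrix <- function(records, nmaf_min = 0.05, maf_min = 0.05,
                                str_call_rate_min = 0.99) {
  stopifnot(inherits(records, "variant_records"))
  info <- records$info
  n_var <- nrow(info)
  keep <- logical(n_var)
  reason <- character(n_var)
  nmaf <- call_rate <- rep(NA_real_, n_var)
  dosages <- matrix(NA_real_, n_var, length(records$samples),
                    dimnames = list(info$id, records$samples))
  for (i in seq_len(n_var)) {
    raw_i <- records$raw[i, ]
    call_rate[i] <- mean(!is_missing_field(raw_i))
    if (call_rate[i] == 0) { reason[i] <- "all_missing"; next }
    nmaf[i] <- non_mode_allele_freq(raw_i, info$encoding[i])
    freq_min <- if (info$variant_class[i] %in% c("SNV", "indel")) maf_min else nmaf_min
    if (nmaf[i] < freq_min) { reason[i] <- "frequency"; next }
    if (info$variant_class[i] == "STR" && call_rate[i] < str_call_rate_min) {
      reason[i] <- "call_rate"; next
    }
    d <- raw_to_dosage(raw_i, info$encoding[i])
    if (info$encoding[i] != "biallelic_gt") d <- rank_scale_02(d)
    d[is.na(d)] <- mean(d, na.rm = TRUE)
    dosages[i, ] <- d
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no variants pass filters")
  variants <- info[keep, , drop = FALSE]
  variants$nmaf <- nmaf[keep]
  variants$call_rate <- call_rate[keep]
  rownames(variants) <- NULL
  structure(list(dosages = dosages[keep, , drop = FALSE],
                 variants = variants,
                 samples = records$samples,
                 dropped = data.frame(id = info$id[!keep],
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE),
                 thresholds = list(nmaf_min = nmaf_min, maf_min = maf_min,
                                   str_call_rate_min = str_call_rate_min)),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", nrow(x$dosages), "variants x", length(x$samples),
      "samples (", nrow(x$dropped), "dropped )\n")
  invisible(x)
}
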