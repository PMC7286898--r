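# Readers and writers for the standard formats the pipeline exchanges:
# VCF with caller-style FORMAT fields (GB/CN/AB/GT), GTF gene models, BEDPE
# loops, and TSV matrices.

#' Write variant records to VCF
#'
#' One VCF with a per-record FORMAT matching the variant's raw encoding:
#' \code{GB} (STR per-allele bp differences), \code{CN} (integer diploid
#' copy number), \code{AB} (allele-balance fraction) or \code{GT}.
#' Coordinates are converted from the internal 0-based half-open convention
#' to 1-based POS with an \code{END} INFO key.
#'
#' @param records a \code{\link{variant_records}} object.
#' @param path output file.
#' @export
write_variant_vcf <- function(records, path) {
  info <- records$info
  fmt_key <- c(str_gb = "GB", copy_number = "CN", allele_balance = "AB",
               biallelic_gt = "GT")[info$encoding]
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Variant length\">",
    "##INFO=<ID=CLUSTER,Number=1,Type=String,Description=\"Redundancy cluster id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GB,Number=1,Type=String,Description=\"STR allele bp differences\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Diploid copy number\">",
    "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", records$samples), collapse = "\t"))
  info_col <- paste0("SVTYPE=", info$variant_class, ";END=", info$end,
                     ";SVLEN=", info$length,
                     ifelse(is.na(info$cluster_id), "",
                            paste0(";CLUSTER=", info$cluster_id)))
  body <- vapply(seq_len(nrow(info)), function(i) {
    paste(c(info$chrom[i], info$start[i] + 1L, info$id[i], "N",
            paste0("<", info$variant_class[i], ">"), ".", "PASS",
            info_col[i], fmt_key[i], records$raw[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant records from VCF
#'
#' Inverse of \code{\link{write_variant_vcf}}, using \pkg{vcfR} for parsing.
#' The per-record FORMAT key determines each variant's raw encoding.
#'
#' @param path VCF file.
#' @return a \code{\link{variant_records}} object.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  get_info <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(?<=", key, "=)[^;]+"),
                                      fix$INFO, perl = TRUE))
    out <- rep(NA_character_, nrow(fix))
    has <- grepl(paste0(key, "="), fix$INFO, fixed = TRUE)
    out[has] <- m
    out
  }
  fmt <- v@gt[, "FORMAT"]
  encoding <- c(GB = "str_gb", CN = "copy_number", AB = "allele_balance",
                GT = "biallelic_gt")[fmt]
  info <- data.frame(
    id = fix$ID, variant_class = get_info("SVTYPE"), chrom = fix$CHROM,
    start = as.numeric(fix$POS) - 1, end = as.numeric(get_info("END")),
    length = as.numeric(get_info("SVLEN")), encoding = unname(encoding),
    cluster_id = get_info("CLUSTER"), stringsAsFactors = FALSE)
  raw <- v@gt[, -1, drop = FALSE]
  raw[is.na(raw)] <- "."
  rownames(raw) <- info$id
  variant_records(info, raw)
}

#' Write gene models to GTF
#'
#' Emits gene and exon features via \pkg{rtracklayer} (1-based inclusive
#' coordinates, \code{gene_id} and \code{gene_type} attributes).
#'
#' @param models a \code{\link{gene_models}} object.
#' @param path output GTF file.
#' @export
write_gene_models_gtf <- function(models, path) {
  g <- models$genes
  e <- models$exons
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, type = "gene", gene_id = g$id,
    gene_type = g$gene_type %||% "protein_coding")
  est <- g$strand[match(e$gene_id, g$id)]
  gr_exons <- GenomicRanges::GRanges(
    seqnames = g$chrom[match(e$gene_id, g$id)],
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = est, type = "exon", gene_id = e$gene_id,
    gene_type = g$gene_type[match(e$gene_id, g$id)] %||% "protein_coding")
  rtracklayer::export(c(gr_genes, gr_exons), path, format = "gtf")
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports gene and exon features (Gencode-style \code{gene_id} /
#' \code{gene_type} attributes) and derives TSS and strand-aware promoters.
#'
#' @param path GTF file.
#' @param ... promoter window arguments passed to \code{\link{gene_models}}.
#' @return a \code{\link{gene_models}} object.
#' @export
read_gene_models <- function(path, ...) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  gdf <- df[df$type == "gene", ]
  strand <- as.character(gdf$strand)
  start0 <- gdf$start - 1L
  genes <- data.frame(
    id = gdf$gene_id, chrom = as.character(gdf$seqnames), strand = strand,
    start = start0, end = gdf$end,
    tss = ifelse(strand == "-", gdf$end - 1L, start0),
    gene_type = if (!is.null(gdf$gene_type)) gdf$gene_type else "protein_coding",
    stringsAsFactors = FALSE)
  edf <- df[df$type == "exon", ]
  exons <- data.frame(gene_id = edf$gene_id, start = edf$start - 1L,
                      end = edf$end, stringsAsFactors = FALSE)
  gene_models(genes, exons, ...)
}

#' Write loops to BEDPE
#'
#' Standard headerless BEDPE: both anchors as 0-based half-open intervals,
#' the loop id in the name column and the linked gene id in column 8.
#'
#' @param loops loop data.frame.
#' @param path output file.
#' @export
write_loops_bedpe <- function(loops, path) {
  out <- data.frame(loops$chrom, loops$p_start, loops$p_end,
                    loops$chrom, loops$d_start, loops$d_end,
                    loops$loop_id, loops$gene)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read loops from BEDPE
#'
#' @param path BEDPE file with the promoter anchor in columns 1-3, the
#'   distal anchor in columns 4-6, loop id in column 7 and gene id in
#'   column 8.
#' @return loop data.frame as produced by \code{\link{simulate_loops}}.
#' @export
read_loops_bedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(loop_id = as.character(d[[7]]), gene = as.character(d[[8]]),
             chrom = d[[1]], p_start = d[[2]], p_end = d[[3]],
             d_start = d[[5]], d_end = d[[6]], stringsAsFactors = FALSE)
}

write_matrix_tsv <- function(m, path, rowname_header = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- rowname_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Serialize a synthetic cohort to plain-text files
#'
#' Writes every component in its standard format: variants to VCF, gene
#' models to GTF, loops to BEDPE, and expression / kinship / GWAS panel /
#' truth tables to TSV.
#'
#' @param cohort an \code{sv_cohort} from \code{\link{simulate_cohort}}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_variant_vcf(cohort$variants, p("variants.vcf"))
  write_gene_models_gtf(cohort$genes, p("genes.gtf"))
  write_loops_bedpe(cohort$loops, p("loops.bedpe"))
  write_matrix_tsv(cohort$expression, p("expression_tpm.tsv"), "gene")
  write_matrix_tsv(cohort$kinship, p("kinship.tsv"), "sample")
  utils::write.table(cohort$genes$genes, p("gene_metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gwas$snvs, p("gwas_snvs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$gwas$dosages, p("gwas_dosages.tsv"), "snv")
  utils::write.table(cohort$gwas$traits, p("gwas_traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$planted_effects, p("truth_planted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$trait_links, p("truth_trait_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
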