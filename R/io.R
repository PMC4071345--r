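# Readers and writers for the plain-text interchange formats: minimal VCF
# with per-sample allele depths, long allele-count TSV, homology hit tables
# and gene-position tables.

SAMPLE_NAMES <- c(resistant = "XenR", susceptible = "FRA", bulk = "SelBC")

counts_to_refalt <- function(counts) {
  res_alt <- counts$res_is_alt
  pick <- function(res, sus) list(ref = ifelse(res_alt, sus, res),
                                  alt = ifelse(res_alt, res, sus))
  x <- pick(counts$xenr_res, counts$xenr_sus)
  f <- pick(counts$fra_res, counts$fra_sus)
  b <- pick(counts$bulk_res, counts$bulk_sus)
  data.frame(unigene = counts$unigene, pos = counts$pos_in_unigene,
             ref = counts$ref, alt = counts$alt,
             xenr_ref = x$ref, xenr_alt = x$alt,
             fra_ref = f$ref, fra_alt = f$alt,
             bulk_ref = b$ref, bulk_alt = b$alt,
             stringsAsFactors = FALSE)
}

#' Convert simulated bulk counts to a variant-record table in memory
#'
#' Equivalent to writing the counts with [write_allele_counts()] and
#' reading them back with [read_variant_table()], without touching disk.
#'
#' @param counts a `bulk_counts` object from [simulate_bulk_counts()]
#' @return a `variant_records` data frame
#' @export
counts_to_records <- function(counts) {
  w <- counts_to_refalt(counts)
  out <- data.frame(unigene = w$unigene, pos = w$pos, ref = w$ref,
                    alt = w$alt,
                    rp_ref = as.integer(w$xenr_ref),
                    rp_alt = as.integer(w$xenr_alt),
                    sp_ref = as.integer(w$fra_ref),
                    sp_alt = as.integer(w$fra_alt),
                    bulk_ref = as.integer(w$bulk_ref),
                    bulk_alt = as.integer(w$bulk_alt),
                    stringsAsFactors = FALSE)
  out <- out[order(out$unigene, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Write simulated allele counts as a long TSV
#'
#' One row per (variant, sample): columns unigene, pos, ref, alt, sample,
#' ref_count, alt_count.  Sample names follow the resistant parent /
#' susceptible parent / selected bulk convention (`XenR`, `FRA`, `SelBC`).
#'
#' @param counts a `bulk_counts` object from [simulate_bulk_counts()]
#' @param path output file
#' @param comments character vector written as leading `#` comment lines
#' @return `path`, invisibly
#' @export
write_allele_counts <- function(counts, path, comments = character()) {
  w <- counts_to_refalt(counts)
  long <- do.call(rbind, lapply(seq_along(SAMPLE_NAMES), function(i) {
    pre <- c("xenr", "fra", "bulk")[i]
    data.frame(unigene = w$unigene, pos = w$pos, ref = w$ref, alt = w$alt,
               sample = unname(SAMPLE_NAMES[i]),
               ref_count = w[[paste0(pre, "_ref")]],
               alt_count = w[[paste0(pre, "_alt")]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$unigene, long$pos, long$sample), ]
  write_tsv_commented(long, path, comments)
}

#' Write simulated allele counts as a minimal VCF v4.2 with AD genotypes
#'
#' The transcript (unigene) plays the role of the contig; positions are
#' 1-based transcript coordinates.
#'
#' @inheritParams write_allele_counts
#' @return `path`, invisibly
#' @export
write_vcf <- function(counts, path) {
  w <- counts_to_refalt(counts)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsascan",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths for the ref and alt alleles">',
    sprintf("##contig=<ID=%s>", unique(w$unigene)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(SAMPLE_NAMES)), collapse = "\t")
  ), con)
  ad <- function(r, a) paste(r, a, sep = ",")
  rows <- paste(w$unigene, w$pos, ".", w$ref, w$alt, ".", "PASS", ".", "AD",
                ad(w$xenr_ref, w$xenr_alt), ad(w$fra_ref, w$fra_alt),
                ad(w$bulk_ref, w$bulk_alt), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Write a pair of directional homology hit tables
#'
#' @param hits list with `forward` and `reverse` data frames from
#'   [generate_hit_tables()]
#' @param fwd_path,rev_path output files (tab-separated, with header)
#' @return invisibly, the two paths
#' @export
write_hit_tables <- function(hits, fwd_path, rev_path) {
  write_tsv_commented(hits$forward, fwd_path)
  write_tsv_commented(hits$reverse, rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Write the reference gene-position table
#'
#' @param genes data frame with gene, chrom, start, end, strand (the
#'   `genes` element of a `genome_map` works directly)
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_gene_positions <- function(genes, path) {
  write_tsv_commented(genes[, c("gene", "chrom", "start", "end", "strand")],
                      path)
}

#' Read a gene-position TSV
#' @param path TSV with columns gene, chrom, start, end (strand optional)
#' @return data frame
#' @export
read_gene_positions <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop("gene-position table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a homology hit table (tabular format)
#' @param path TSV with columns qseqid, sseqid, bitscore, evalue (at least)
#' @return data frame
#' @export
read_hit_table <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("qseqid", "sseqid", "bitscore", "evalue")
  if (!all(need %in% names(df))) {
    stop("hit table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read per-sample SNP allele counts into a variant-record table
#'
#' Accepts either the long allele-count TSV written by
#' [write_allele_counts()] or a minimal VCF with per-sample AD depths.
#' Multiallelic records and indels are dropped (the fixation index is
#' defined over biallelic SNPs only).
#'
#' @param path input file
#' @param dialect `"tsv"` or `"vcf"`
#' @param samples named character vector mapping roles
#'   (resistant / susceptible / bulk) to sample names in the file
#' @return data frame of class `variant_records` with columns unigene, pos,
#'   ref, alt and ref/alt counts `rp_ref`, `rp_alt`, `sp_ref`, `sp_alt`,
#'   `bulk_ref`, `bulk_alt`
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               samples = SAMPLE_NAMES) {
  dialect <- match.arg(dialect)
  need <- c("resistant", "susceptible", "bulk")
  if (!all(need %in% names(samples))) {
    stop("`samples` must name resistant, susceptible and bulk", call. = FALSE)
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- switch(dialect,
                tsv = read_variants_tsv(path, samples),
                vcf = read_variants_vcf(path, samples))
  out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L, , drop = FALSE]
  out <- out[order(out$unigene, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_records", "data.frame")
  out
}

read_variants_tsv <- function(path, samples) {
  df <- read_tsv_commented(path, colClasses = "character")
  need <- c("unigene", "pos", "ref", "alt", "sample", "ref_count", "alt_count")
  if (!all(need %in% names(df))) {
    stop("allele-count TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(empty_variant_records())
  num <- suppressWarnings(cbind(pos = as.integer(df$pos),
                                ref_count = as.integer(df$ref_count),
                                alt_count = as.integer(df$alt_count)))
  bad <- which(rowSums(is.na(num)) > 0 | num[, "ref_count"] < 0 |
                 num[, "alt_count"] < 0)
  if (length(bad)) {
    stop("malformed allele-count rows (file line numbers, counting the ",
         "header): ", paste(utils::head(bad + 1L, 10), collapse = ", "),
         call. = FALSE)
  }
  df$pos <- num[, "pos"]; df$ref_count <- num[, "ref_count"]
  df$alt_count <- num[, "alt_count"]

  missing <- setdiff(samples, unique(df$sample))
  if (length(missing)) {
    stop("sample(s) absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$unigene, df$pos, sep = "\r")
  base <- df[!duplicated(key), c("unigene", "pos", "ref", "alt")]
  bkey <- key[!duplicated(key)]
  grab <- function(role, col) {
    sub <- df[df$sample == samples[[role]], ]
    sub[[col]][match(bkey, paste(sub$unigene, sub$pos, sep = "\r"))]
  }
  out <- data.frame(base,
                    rp_ref = grab("resistant", "ref_count"),
                    rp_alt = grab("resistant", "alt_count"),
                    sp_ref = grab("susceptible", "ref_count"),
                    sp_alt = grab("susceptible", "alt_count"),
                    bulk_ref = grab("bulk", "ref_count"),
                    bulk_alt = grab("bulk", "alt_count"),
                    stringsAsFactors = FALSE)
  if (anyNA(out[, -(1:4)])) {
    stop("some variants lack counts for one or more samples", call. = FALSE)
  }
  out
}

read_variants_vcf <- function(path, samples) {
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) == 0L) return(empty_variant_records())
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- rr$ALT
  biallelic <- lengths(alt) == 1L
  vcf <- vcf[biallelic, ]
  rr <- rr[biallelic, ]
  if (nrow(vcf) == 0L) return(empty_variant_records())
  sn <- colnames(vcf)
  missing <- setdiff(samples, sn)
  if (length(missing)) {
    stop("sample(s) absent from VCF: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD FORMAT field", call. = FALSE)
  get_ad <- function(sample, k) {
    j <- match(sample, sn)
    if (is.list(ad)) {
      vapply(ad[, j], function(v) as.integer(v[k]), 1L)
    } else {
      as.integer(ad[, j, k])
    }
  }
  data.frame(
    unigene = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(unlist(alt)),
    rp_ref = get_ad(samples[["resistant"]], 1L),
    rp_alt = get_ad(samples[["resistant"]], 2L),
    sp_ref = get_ad(samples[["susceptible"]], 1L),
    sp_alt = get_ad(samples[["susceptible"]], 2L),
    bulk_ref = get_ad(samples[["bulk"]], 1L),
    bulk_alt = get_ad(samples[["bulk"]], 2L),
    stringsAsFactors = FALSE
  )
}

empty_variant_records <- function() {
  data.frame(unigene = character(), pos = integer(), ref = character(),
             alt = character(), rp_ref = integer(), rp_alt = integer(),
             sp_ref = integer(), sp_alt = integer(), bulk_ref = integer(),
             bulk_alt = integer(), stringsAsFactors = FALSE)
}
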