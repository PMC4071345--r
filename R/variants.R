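# Informative-SNP calling from parental and bulk allele counts, and
# detection of the zero-coverage deletion footprint with its consequence on
# the encoded protein.

#' Is an allele fixed in the selected bulk?
#'
#' Strictly-greater comparison against the fixation threshold: a frequency
#' of exactly 0.95 is not fixed.
#'
#' @param frequency bulk frequency of the resistant-parent allele, in \[0,1\]
#'   (NA allowed, propagates)
#' @param threshold fixation threshold (default 0.95)
#' @return logical vector
#' @export
is_fixed <- function(frequency, threshold = 0.95) {
  ok <- is.na(frequency) | (frequency >= 0 & frequency <= 1)
  if (!all(ok)) stop("`frequency` must lie in [0,1]", call. = FALSE)
  frequency > threshold
}

#' Call informative SNPs and their bulk allele frequency
#'
#' A variant is informative when both parental samples are sufficiently
#' covered and near-homozygous for opposite alleles.  For each informative
#' SNP the resistant-parent allele is recorded and its frequency in the
#' selected bulk is computed; the frequency is NA when bulk coverage is
#' below `min_bulk_cov`.
#'
#' @param records a `variant_records` table from [read_variant_table()]
#' @param min_parent_cov minimum read depth in each parent (default 10)
#' @param parent_purity minimum major-allele frequency in each parent
#'   (default 0.9)
#' @param min_bulk_cov minimum bulk depth for a defined frequency
#'   (default 20)
#' @param fix_threshold fixation threshold passed to [is_fixed()]
#' @return data frame of class `informative_snps`: unigene, pos, res_allele
#'   (`"ref"` or `"alt"`), bulk_freq, fixed
#' @export
call_informative <- function(records, min_parent_cov = 10,
                             parent_purity = 0.9, min_bulk_cov = 20,
                             fix_threshold = 0.95) {
  stop_if_not_fraction(parent_purity, "parent_purity")
  rp_cov <- records$rp_ref + records$rp_alt
  sp_cov <- records$sp_ref + records$sp_alt
  rp_alt_f <- ifelse(rp_cov > 0, records$rp_alt / rp_cov, NA_real_)
  sp_alt_f <- ifelse(sp_cov > 0, records$sp_alt / sp_cov, NA_real_)
  rp_allele <- ifelse(rp_alt_f >= 0.5, "alt", "ref")
  sp_allele <- ifelse(sp_alt_f >= 0.5, "alt", "ref")
  rp_major_f <- pmax(rp_alt_f, 1 - rp_alt_f)
  sp_major_f <- pmax(sp_alt_f, 1 - sp_alt_f)
  keep <- !is.na(rp_major_f) & !is.na(sp_major_f) &
    rp_cov >= min_parent_cov & sp_cov >= min_parent_cov &
    rp_major_f >= parent_purity & sp_major_f >= parent_purity &
    rp_allele != sp_allele
  out <- records[keep, c("unigene", "pos"), drop = FALSE]
  res_allele <- rp_allele[keep]
  bulk_cov <- records$bulk_ref[keep] + records$bulk_alt[keep]
  res_reads <- ifelse(res_allele == "alt", records$bulk_alt[keep],
                      records$bulk_ref[keep])
  out$res_allele <- res_allele
  out$bulk_freq <- ifelse(bulk_cov >= min_bulk_cov, res_reads / bulk_cov,
                          NA_real_)
  out$fixed <- is_fixed(out$bulk_freq, fix_threshold)
  rownames(out) <- NULL
  class(out) <- c("informative_snps", "data.frame")
  out
}

#' Write an informative-SNP table
#' @param snps an `informative_snps` data frame
#' @param path output TSV
#' @param comments leading `#` comment lines
#' @return `path`, invisibly
#' @export
write_informative_snps <- function(snps, path, comments = character()) {
  write_tsv_commented(as.data.frame(snps), path, comments)
}

#' Read an informative-SNP table written by [write_informative_snps()]
#' @param path TSV with columns unigene, pos, res_allele, bulk_freq, fixed
#' @return an `informative_snps` data frame
#' @export
read_informative_snps <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("unigene", "pos", "res_allele", "bulk_freq", "fixed")
  if (!all(need %in% names(df))) {
    stop("informative-SNP table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$fixed <- as.logical(df$fixed)
  class(df) <- c("informative_snps", "data.frame")
  df
}

#' Scan paired coverage tracks for a homozygous-deletion footprint
#'
#' Reports the maximal intervals of length at least `min_len` where the
#' resistant-bulk coverage never exceeds `max_res_cov` while the
#' susceptible track averages at least `min_sus_cov` over the interval —
#' the signature of a deletion that is homozygous in the selected material
#' but absent from the susceptible parent.
#'
#' @param res_track numeric vector: per-position depth in the resistant bulk
#' @param sus_track numeric vector of equal length: susceptible depth
#' @param min_len minimum interval length, bp (default 50)
#' @param min_sus_cov minimum susceptible mean depth over the interval
#'   (default 10)
#' @param max_res_cov maximum tolerated resistant depth inside the interval
#'   (default 0: literally no read maps inside)
#' @return data frame with columns start, end, length, sus_mean_cov,
#'   res_max_cov; zero rows when nothing qualifies
#' @export
deletion_scan <- function(res_track, sus_track, min_len = 50,
                          min_sus_cov = 10, max_res_cov = 0) {
  if (length(res_track) != length(sus_track)) {
    stop("coverage tracks must have equal length", call. = FALSE)
  }
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      sus_mean_cov = numeric(), res_max_cov = numeric())
  if (length(res_track) == 0L) return(empty)
  r <- rle(res_track <= max_res_cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  if (!length(keep)) return(empty)
  calls <- lapply(keep, function(i) {
    s <- starts[i]; e <- ends[i]
    sus_mean <- mean(sus_track[s:e])
    if (sus_mean < min_sus_cov) return(NULL)
    data.frame(start = s, end = e, length = e - s + 1L,
               sus_mean_cov = sus_mean,
               res_max_cov = max(res_track[s:e]))
  })
  calls <- calls[!vapply(calls, is.null, TRUE)]
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}

#' Consequence of a transcript deletion on the encoded protein
#'
#' Intersects the deletion with the CDS. A coding overlap divisible by 3
#' removes `overlap/3` amino acids in frame; any other coding overlap
#' shifts the reading frame, which can create a premature stop.  A deletion
#' entirely in the UTRs is a zero-effect result, not an error.
#'
#' @param cds_interval `c(start, end)` of the CDS on the transcript,
#'   1-based inclusive
#' @param del_interval `c(start, end)` of the deletion, same coordinates
#' @return list with `coding_overlap` (nt), `in_frame`, `aa_removed`
#'   (0 when frameshifted or no coding overlap) and
#'   `premature_stop_possible`
#' @export
deletion_protein_effect <- function(cds_interval, del_interval) {
  stopifnot(length(cds_interval) == 2L, length(del_interval) == 2L)
  if (cds_interval[1] > cds_interval[2] || del_interval[1] > del_interval[2]) {
    stop("intervals must satisfy start <= end", call. = FALSE)
  }
  ov <- max(0L, min(cds_interval[2], del_interval[2]) -
              max(cds_interval[1], del_interval[1]) + 1L)
  in_frame <- ov %% 3L == 0L
  list(coding_overlap = as.integer(ov),
       in_frame = in_frame,
       aa_removed = if (in_frame) as.integer(ov %/% 3L) else 0L,
       premature_stop_possible = ov > 0L && !in_frame)
}
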