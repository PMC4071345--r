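# Transcriptome bookkeeping: RPKM, the four-criterion unigene filter, and
# longest-unigene-per-cluster representative selection.

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param read_count mapped reads for the unigene (>= 0)
#' @param length transcript length in bp (>= 1)
#' @param total_mapped total mapped reads in the library (>= 1)
#' @return RPKM value(s)
#' @export
rpkm <- function(read_count, length, total_mapped) {
  if (any(length < 1)) stop("`length` must be >= 1", call. = FALSE)
  if (any(total_mapped < 1)) stop("`total_mapped` must be >= 1", call. = FALSE)
  if (any(read_count < 0)) stop("`read_count` must be >= 0", call. = FALSE)
  read_count / (length / 1000) / (total_mapped / 1e6)
}

#' Keep informative unigenes by the four-criterion disjunction
#'
#' A unigene is kept when it satisfies at least one of: it has a CDS, it
#' has a homology match against a reference proteome, it is expressed
#' above `rpkm_min` (strict), or it is longer than `len_min` bp (strict).
#'
#' @param annotations data frame with columns unigene, length, has_cds,
#'   has_homolog, read_count
#' @param total_mapped total mapped reads used for RPKM
#' @param rpkm_min expression threshold (default 0.25 RPKM, strict >)
#' @param len_min length threshold (default 500 bp, strict >)
#' @return the annotation rows kept, with an added `rpkm` column
#' @export
filter_unigenes <- function(annotations, total_mapped, rpkm_min = 0.25,
                            len_min = 500) {
  need <- c("unigene", "length", "has_cds", "has_homolog", "read_count")
  if (!all(need %in% names(annotations))) {
    stop("annotations must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  annotations$rpkm <- rpkm(annotations$read_count, annotations$length,
                           total_mapped)
  keep <- annotations$has_cds | annotations$has_homolog |
    annotations$rpkm > rpkm_min | annotations$length > len_min
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick the longest unigene of each cluster as its representative
#'
#' Length ties go to the lexicographically smallest unigene id so the
#' choice is reproducible.
#'
#' @param annotations data frame with columns unigene, cluster, length
#' @return one row per cluster, ordered by cluster id
#' @export
cluster_representative <- function(annotations) {
  need <- c("unigene", "cluster", "length")
  if (!all(need %in% names(annotations))) {
    stop("annotations must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  o <- order(annotations$cluster, -annotations$length, annotations$unigene)
  a <- annotations[o, , drop = FALSE]
  out <- a[!duplicated(a$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}
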