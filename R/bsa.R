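# Asymmetric single-bulk BSA: per-unigene fixation index, placement of
# unigenes on a reference genome via reciprocal best hits, rolling-window
# smoothing over consecutive orthologs, and candidate-region calling.

#' Fixation index of one unigene
#'
#' The index is the ratio of informative SNPs whose resistant-parent allele
#' is fixed in the selected bulk (frequency strictly above the fixation
#' threshold) to the total number of informative SNPs with a defined bulk
#' frequency.  It runs from 0 (no distortion) to 1 (all SNPs fixed for the
#' resistant allele).
#'
#' @param snps `informative_snps` rows for a single unigene
#' @param min_snps minimum number of frequency-defined SNPs for the index
#'   to be defined (default 1)
#' @return one-row data frame: unigene, n_snps, n_fixed, index (NA when
#'   n_snps < min_snps)
#' @export
bsa_index <- function(snps, min_snps = 1L) {
  u <- unique(snps$unigene)
  if (length(u) > 1L) stop("SNPs from more than one unigene", call. = FALSE)
  if (length(u) == 0L) u <- NA_character_
  defined <- !is.na(snps$bulk_freq)
  n <- sum(defined)
  nf <- sum(snps$fixed[defined])
  data.frame(unigene = u, n_snps = n, n_fixed = nf,
             index = if (n >= min_snps && n > 0L) nf / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Fixation index for every unigene in an informative-SNP table
#'
#' @param snps an `informative_snps` data frame
#' @param min_snps minimum SNPs per unigene for a defined index
#' @return data frame with one row per unigene (unigene, n_snps, n_fixed,
#'   index)
#' @export
bsa_index_table <- function(snps, min_snps = 1L) {
  if (nrow(snps) == 0L) {
    return(data.frame(unigene = character(), n_snps = integer(),
                      n_fixed = integer(), index = numeric()))
  }
  parts <- split(seq_len(nrow(snps)), snps$unigene)
  out <- do.call(rbind, lapply(parts, function(i) {
    bsa_index(snps[i, , drop = FALSE], min_snps = min_snps)
  }))
  rownames(out) <- NULL
  out[order(out$unigene), , drop = FALSE]
}

best_hit_per_query <- function(hits) {
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), c("qseqid", "sseqid"), drop = FALSE]
}

#' Reciprocal best hits between two directional homology hit tables
#'
#' A pair (unigene, gene) is reported iff the gene is the unigene's best
#' hit in the forward table and the unigene is the gene's best hit in the
#' reverse table.  Ties are broken by bitscore (descending), then e-value
#' (ascending), then subject id (lexicographic), so output is reproducible.
#'
#' @param forward hit table unigene -> reference gene
#'   (columns qseqid, sseqid, bitscore, evalue)
#' @param reverse hit table reference gene -> unigene
#' @return data frame with columns unigene, gene; sorted by unigene
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  empty <- data.frame(unigene = character(), gene = character(),
                      stringsAsFactors = FALSE)
  if (is.null(forward) || is.null(reverse) ||
      nrow(forward) == 0L || nrow(reverse) == 0L) return(empty)
  fb <- best_hit_per_query(forward)
  rb <- best_hit_per_query(reverse)
  back <- rb$sseqid[match(fb$sseqid, rb$qseqid)]
  keep <- !is.na(back) & back == fb$qseqid
  out <- data.frame(unigene = fb$qseqid[keep], gene = fb$sseqid[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$unigene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place unigenes on the reference genome through their orthologs
#'
#' Each RBH-paired unigene inherits the chromosome and coordinates of its
#' reference-genome ortholog.  Anchors are sorted by (chromosome, start)
#' and ranked consecutively within each chromosome.  Pairs whose gene has
#' no position record are dropped with a warning.
#'
#' @param pairs data frame from [reciprocal_best_hits()]
#' @param gene_positions data frame with gene, chrom, start, end
#' @return data frame of class `anchors`: unigene, gene, chrom, start, end,
#'   rank
#' @export
anchor_unigenes <- function(pairs, gene_positions) {
  m <- match(pairs$gene, gene_positions$gene)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " ortholog pair(s) dropped: gene absent from ",
            "the position table")
  }
  keep <- !is.na(m)
  out <- data.frame(unigene = pairs$unigene[keep], gene = pairs$gene[keep],
                    chrom = gene_positions$chrom[m[keep]],
                    start = gene_positions$start[m[keep]],
                    end = gene_positions$end[m[keep]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$unigene), , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("anchors", "data.frame")
  out
}

#' Rolling-window means of the fixation index over consecutive orthologs
#'
#' Windows slide with stride 1 over ortholog rank (not base pairs): the
#' k-th window on a chromosome averages the indexes of anchored unigenes
#' k .. k+window_size-1 in genome order.  Unigenes with an undefined index
#' are removed before ranking, so they neither contribute to nor interrupt
#' windows.  Chromosomes with fewer anchored unigenes than `window_size`
#' produce no windows.
#'
#' @param anchors an `anchors` data frame
#' @param index_table output of [bsa_index_table()]
#' @param window_size number of consecutive orthologs per window (default 3)
#' @return data frame of class `bsa_windows`: chrom, win_start_rank,
#'   win_end_rank, mean_index, span_start, span_end, unigenes
#'   (comma-separated member ids)
#' @export
rolling_windows <- function(anchors, index_table, window_size = 3L) {
  stop_if_not_scalar_count(window_size, "window_size")
  a <- merge(as.data.frame(anchors), index_table, by = "unigene")
  a <- a[!is.na(a$index), , drop = FALSE]
  a <- a[order(a$chrom, a$start, a$unigene), , drop = FALSE]
  # re-rank over the unigenes that actually carry an index
  a$rank <- stats::ave(seq_len(nrow(a)), a$chrom, FUN = seq_along)
  parts <- split(a, a$chrom)
  res <- lapply(parts, function(ch) {
    n <- nrow(ch)
    if (n < window_size) return(NULL)
    i <- seq_len(n - window_size + 1L)
    idx <- ch$index
    csum <- cumsum(c(0, idx))
    data.frame(
      chrom = ch$chrom[1],
      win_start_rank = i,
      win_end_rank = i + window_size - 1L,
      mean_index = (csum[i + window_size] - csum[i]) / window_size,
      span_start = vapply(i, function(k) min(ch$start[k:(k + window_size - 1L)]), 1),
      span_end = vapply(i, function(k) max(ch$end[k:(k + window_size - 1L)]), 1),
      unigenes = vapply(i, function(k) {
        paste(ch$unigene[k:(k + window_size - 1L)], collapse = ",")
      }, ""),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), win_start_rank = integer(),
                      win_end_rank = integer(), mean_index = numeric(),
                      span_start = numeric(), span_end = numeric(),
                      unigenes = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("bsa_windows", "data.frame")
  out
}

#' Call candidate regions from above-threshold windows
#'
#' Maximal runs of rank-consecutive windows whose mean index is strictly
#' above the threshold are merged into one region per run.  A region spans
#' from the smallest member-anchor start to the largest member-anchor end
#' and counts its distinct member unigenes.
#'
#' @param windows a `bsa_windows` data frame
#' @param threshold region-calling threshold on the window mean
#'   (default 0.60, strict)
#' @return data frame of class `bsa_regions`: chrom, span_start, span_end,
#'   n_unigenes, n_windows, peak_mean_index, unigenes; sorted by
#'   (chrom, span_start)
#' @export
call_regions <- function(windows, threshold = 0.60) {
  empty <- data.frame(chrom = character(), span_start = numeric(),
                      span_end = numeric(), n_unigenes = integer(),
                      n_windows = integer(), peak_mean_index = numeric(),
                      unigenes = character(), stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) { class(empty) <- c("bsa_regions", "data.frame"); return(empty) }
  parts <- split(as.data.frame(windows), windows$chrom)
  res <- lapply(parts, function(ch) {
    ch <- ch[order(ch$win_start_rank), , drop = FALSE]
    hot <- ch$mean_index > threshold
    if (!any(hot)) return(NULL)
    # break runs where window ranks are not consecutive or 'hot' drops
    grp <- cumsum(!hot | c(TRUE, diff(ch$win_start_rank) != 1L))
    runs <- split(which(hot), grp[hot])
    do.call(rbind, lapply(runs, function(ii) {
      mem <- unique(unlist(strsplit(ch$unigenes[ii], ",", fixed = TRUE)))
      data.frame(chrom = ch$chrom[1],
                 span_start = min(ch$span_start[ii]),
                 span_end = max(ch$span_end[ii]),
                 n_unigenes = length(mem),
                 n_windows = length(ii),
                 peak_mean_index = max(ch$mean_index[ii]),
                 unigenes = paste(mem, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out)) { class(empty) <- c("bsa_regions", "data.frame"); return(empty) }
  out <- out[order(out$chrom, out$span_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bsa_regions", "data.frame")
  out
}

#' Top-ranked candidate region
#'
#' Regions are ranked by peak window mean, then by number of member
#' windows, then by number of member unigenes (a sustained wide signal
#' outranks an isolated spike of equal height).
#'
#' @param regions a `bsa_regions` data frame
#' @return the single top-ranked row, or NULL when there are no regions
#' @export
top_region <- function(regions) {
  if (nrow(regions) == 0L) return(NULL)
  o <- order(-regions$peak_mean_index, -regions$n_windows,
             -regions$n_unigenes, regions$chrom)
  regions[o[1], , drop = FALSE]
}

#' End-to-end BSA scan from an informative-SNP table to candidate regions
#'
#' Composes [bsa_index_table()], [reciprocal_best_hits()],
#' [anchor_unigenes()], [rolling_windows()] and [call_regions()].
#'
#' @param snps `informative_snps` data frame (or path to its TSV)
#' @param forward_hits,reverse_hits homology hit tables (data frames or
#'   file paths)
#' @param gene_positions gene-position table (data frame or file path)
#' @param window_size orthologs per rolling window
#' @param region_threshold window-mean threshold for region calling
#' @param min_snps minimum SNPs for a defined unigene index
#' @return list of class `bsa_scan`: `index`, `anchors`, `windows`,
#'   `regions`
#' @export
bsa_scan <- function(snps, forward_hits, reverse_hits, gene_positions,
                     window_size = 3L, region_threshold = 0.60,
                     min_snps = 1L) {
  if (is.character(snps)) snps <- read_informative_snps(snps)
  if (is.character(forward_hits)) forward_hits <- read_hit_table(forward_hits)
  if (is.character(reverse_hits)) reverse_hits <- read_hit_table(reverse_hits)
  if (is.character(gene_positions)) gene_positions <- read_gene_positions(gene_positions)
  idx <- bsa_index_table(snps, min_snps = min_snps)
  pairs <- reciprocal_best_hits(forward_hits, reverse_hits)
  anchors <- anchor_unigenes(pairs, gene_positions)
  windows <- rolling_windows(anchors, idx, window_size = window_size)
  regions <- call_regions(windows, threshold = region_threshold)
  structure(list(index = idx, anchors = anchors, windows = windows,
                 regions = regions),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf("bsa_scan: %d unigene indexes, %d anchors, %d windows, %d region(s)\n",
              nrow(x$index), nrow(x$anchors), nrow(x$windows),
              nrow(x$regions)))
  if (nrow(x$regions)) {
    cat("top region:\n")
    top <- x$regions[order(-x$regions$peak_mean_index), ][1, ]
    cat(sprintf("  %s:%d-%d  %d unigenes, peak window mean %.3f\n",
                top$chrom, top$span_start, top$span_end, top$n_unigenes,
                top$peak_mean_index))
  }
  invisible(x)
}

#' Plot the rolling-window fixation index along the reference genome
#'
#' One panel, chromosomes laid side by side on a cumulative coordinate;
#' windows above the region threshold are drawn in red, mirroring the
#' classic BSA genome scan figure.
#'
#' @param windows a `bsa_windows` data frame
#' @param threshold threshold drawn as a horizontal line (default 0.60)
#' @param path optional PNG output path; when NULL, plots on the active
#'   device
#' @return invisibly, the data frame of plotted points
#' @export
plot_bsa_index <- function(windows, threshold = 0.60, path = NULL) {
  w <- as.data.frame(windows)
  if (nrow(w) == 0L) stop("no windows to plot", call. = FALSE)
  chroms <- unique(w$chrom)
  span <- vapply(chroms, function(ch) max(w$span_end[w$chrom == ch]), 1)
  offs <- c(0, cumsum(as.numeric(span)))[seq_along(chroms)]
  names(offs) <- chroms
  w$x <- offs[w$chrom] + (w$span_start + w$span_end) / 2
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(w$x, w$mean_index, pch = 16, cex = 0.6,
                 col = ifelse(w$mean_index > threshold, "red", "grey30"),
                 ylim = c(0, 1), xlab = "reference genome position (bp, cumulative)",
                 ylab = "mean fixation index (rolling window)", xaxt = "n")
  graphics::abline(h = threshold, lty = 2, col = "red")
  mid <- offs + span / 2
  graphics::axis(1, at = mid, labels = chroms, tick = FALSE)
  graphics::abline(v = offs[-1], col = "grey80")
  invisible(w)
}
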