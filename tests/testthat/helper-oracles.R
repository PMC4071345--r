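# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (loops, position-by-position scans) so that they can
# disagree with the vectorized implementations they check.

# rolling means by explicit looping
oracle_rolling_means <- function(idx, k) {
  n <- length(idx)
  if (n < k) return(numeric(0))
  vapply(seq_len(n - k + 1L), function(i) mean(idx[i:(i + k - 1L)]), 1)
}

# runs of consecutive above-threshold windows, as lists of window indices
oracle_region_runs <- function(means, threshold) {
  runs <- list()
  cur <- integer(0)
  for (i in seq_along(means)) {
    if (means[i] > threshold) {
      cur <- c(cur, i)
    } else if (length(cur)) {
      runs[[length(runs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  runs
}

# position-by-position deletion scan
oracle_deletion_scan <- function(res, sus, min_len, min_sus, max_res) {
  n <- length(res)
  out <- NULL
  i <- 1L
  while (i <= n) {
    if (res[i] <= max_res) {
      j <- i
      while (j < n && res[j + 1L] <= max_res) j <- j + 1L
      if (j - i + 1L >= min_len && mean(sus[i:j]) >= min_sus) {
        out <- rbind(out, data.frame(start = i, end = j))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) data.frame(start = integer(), end = integer()) else out
}

# best hit per query with the stated tie-break, by explicit looping
oracle_best_hit <- function(hits, query) {
  h <- hits[hits$qseqid == query, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  best <- h[1, ]
  for (i in seq_len(nrow(h))[-1]) {
    r <- h[i, ]
    better <- r$bitscore > best$bitscore ||
      (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
      (r$bitscore == best$bitscore && r$evalue == best$evalue &&
         r$sseqid < best$sseqid)
    if (better) best <- r
  }
  best$sseqid
}

# two-sided exact binomial p-value by enumeration (the small-sample
# definition: sum the probabilities of all outcomes no more likely than
# the observed one)
oracle_binom_p <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1L] * (1 + 1e-7)])
}

# Haldane map function
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d))

# hand-built genome map with full control over marker genetic positions;
# one unigene per marker, all on one chromosome
make_point_map <- function(gpos, chrom_len = max(gpos) + 0.1,
                           physical_len = 1e6) {
  n <- length(gpos)
  ppos <- as.integer(round(gpos / chrom_len * physical_len)) + seq_len(n)
  ug <- sprintf("ug_c01_%03d", seq_len(n))
  structure(list(
    chromosomes = data.frame(chrom = "chr01", genetic_len = chrom_len,
                             physical_len = physical_len,
                             stringsAsFactors = FALSE),
    markers = data.frame(marker = paste0(ug, "_s01"), unigene = ug,
                         chrom = "chr01", gpos = gpos, ppos = ppos,
                         pos_in_unigene = 1L, stringsAsFactors = FALSE),
    genes = data.frame(gene = sprintf("BGN_c01_%03d", seq_len(n)),
                       unigene = ug, chrom = "chr01", start = ppos,
                       end = ppos + 500L, strand = "+",
                       stringsAsFactors = FALSE)
  ), class = "genome_map")
}

# minimal informative-SNP table
make_snps <- function(unigene, freq, fixed = NULL, pos = seq_along(freq)) {
  if (is.null(fixed)) fixed <- bsascan::is_fixed(freq)
  structure(data.frame(unigene = unigene, pos = pos, res_allele = "alt",
                       bulk_freq = freq, fixed = fixed,
                       stringsAsFactors = FALSE),
            class = c("informative_snps", "data.frame"))
}

# anchors + index table for n unigenes on one chromosome, in rank order
make_anchored_indexes <- function(idx, chrom = "chr01", start0 = 1000L) {
  n <- length(idx)
  ug <- sprintf("u%03d", seq_len(n))
  anchors <- structure(data.frame(
    unigene = ug, gene = sprintf("g%03d", seq_len(n)), chrom = chrom,
    start = start0 + (seq_len(n) - 1L) * 1000L,
    end = start0 + (seq_len(n) - 1L) * 1000L + 500L,
    rank = seq_len(n), stringsAsFactors = FALSE),
    class = c("anchors", "data.frame"))
  index <- data.frame(unigene = ug, n_snps = 4L,
                      n_fixed = as.integer(round(idx * 4)), index = idx,
                      stringsAsFactors = FALSE)
  list(anchors = anchors, index = index)
}
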