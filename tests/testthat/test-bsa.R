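# Fixation index, RBH anchoring, rolling windows and region calling.

test_that("bsa_index is the fixed/total ratio with a min-SNP guard", {
  expect_equal(bsa_index(make_snps("u1", c(0.99, 0.97, 1, 0.98)))$index, 1.0)
  expect_equal(bsa_index(make_snps("u1", rep(0.5, 5)))$index, 0.0)
  x <- bsa_index(make_snps("u1", c(0.99, 0.97, 1, 0.80)))
  expect_equal(x$index, 0.75)
  expect_equal(c(x$n_snps, x$n_fixed), c(4L, 3L))

  # SNPs with undefined frequency are not counted
  y <- bsa_index(make_snps("u1", c(0.99, NA, 0.2)))
  expect_equal(c(y$n_snps, y$index), c(2, 0.5))
  expect_true(is.na(bsa_index(make_snps("u1", c(NA_real_, NA_real_)))$index))
  expect_true(is.na(bsa_index(make_snps("u1", 0.99), min_snps = 3)$index))

  expect_error(bsa_index(make_snps(c("u1", "u2"), c(1, 1))), "one unigene")

  # oracle + bounds/monotonicity over random instances
  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(1:12, 1)
      f <- stats::runif(n)
      got <- bsa_index(make_snps("u", f))$index
      expect_equal(got, mean(f > 0.95))
      expect_gte(got, 0); expect_lte(got, 1)
    }
  })
})

test_that("reciprocal_best_hits keeps mutual best pairs only", {
  fwd <- data.frame(
    qseqid = c("u1", "u1", "u2", "u3"),
    sseqid = c("g5", "g7", "g2", "g9"),
    bitscore = c(900, 500, 700, 600), evalue = c(1e-90, 1e-40, 1e-60, 1e-50),
    stringsAsFactors = FALSE)
  rev <- data.frame(
    qseqid = c("g5", "g2", "g9"),
    sseqid = c("u1", "u2", "u9"),
    bitscore = c(880, 690, 610), evalue = c(1e-88, 1e-58, 1e-51),
    stringsAsFactors = FALSE)
  pairs <- reciprocal_best_hits(fwd, rev)
  expect_equal(pairs, data.frame(unigene = c("u1", "u2"),
                                 gene = c("g5", "g2"),
                                 stringsAsFactors = FALSE))
  # u3 -> g9 but g9's best is u9: excluded

  # deterministic tie-breaks: equal bitscore resolved by evalue then id
  tie <- data.frame(qseqid = "u1", sseqid = c("gB", "gA"),
                    bitscore = c(500, 500), evalue = c(1e-50, 1e-50),
                    stringsAsFactors = FALSE)
  revt <- data.frame(qseqid = c("gA", "gB"), sseqid = c("u1", "u1"),
                     bitscore = c(500, 500), evalue = c(1e-50, 1e-50),
                     stringsAsFactors = FALSE)
  expect_equal(reciprocal_best_hits(tie, revt)$gene, "gA")

  # brute-force best-hit oracle on random tables
  withr::with_seed(42, {
    for (i in 1:50) {
      nq <- sample(3:8, 1)
      f <- data.frame(qseqid = sample(paste0("u", 1:nq), 30, TRUE),
                      sseqid = sample(paste0("g", 1:nq), 30, TRUE),
                      bitscore = sample(100:120, 30, TRUE),
                      evalue = signif(stats::runif(30, 1e-60, 1e-10), 3),
                      stringsAsFactors = FALSE)
      r <- data.frame(qseqid = sample(paste0("g", 1:nq), 30, TRUE),
                      sseqid = sample(paste0("u", 1:nq), 30, TRUE),
                      bitscore = sample(100:120, 30, TRUE),
                      evalue = signif(stats::runif(30, 1e-60, 1e-10), 3),
                      stringsAsFactors = FALSE)
      got <- reciprocal_best_hits(f, r)
      for (q in unique(f$qseqid)) {
        bf <- oracle_best_hit(f, q)
        mutual <- !is.na(bf) && identical(oracle_best_hit(r, bf), q)
        if (mutual) {
          expect_equal(got$gene[got$unigene == q], bf)
        } else {
          expect_false(q %in% got$unigene)
        }
      }
    }
  })
})

test_that("anchor_unigenes sorts, ranks and is order-invariant", {
  pos <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                    chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = c(500, 100, 900, 300),
                    end = c(700, 250, 980, 420), stringsAsFactors = FALSE)
  pairs <- data.frame(unigene = c("u1", "u2", "u3", "u4"),
                      gene = c("gA", "gB", "gC", "gD"),
                      stringsAsFactors = FALSE)
  a <- anchor_unigenes(pairs, pos)
  expect_equal(a$unigene, c("u2", "u1", "u3", "u4"))
  expect_equal(a$rank, c(1L, 2L, 3L, 1L))    # ranks restart per chromosome

  shuffled <- pairs[c(3, 1, 4, 2), ]
  expect_identical(anchor_unigenes(shuffled, pos), a)

  pairs2 <- rbind(pairs, data.frame(unigene = "u9", gene = "gZ"))
  expect_warning(a2 <- anchor_unigenes(pairs2, pos), "absent")
  expect_identical(a2, a)
})

test_that("rolling_windows averages consecutive ortholog indexes", {
  f <- make_anchored_indexes(c(1.0, 0.8, 0.6))
  w <- rolling_windows(f$anchors, f$index, 3)
  expect_equal(nrow(w), 1L)
  expect_equal(w$mean_index, 0.8)
  expect_equal(c(w$win_start_rank, w$win_end_rank), c(1L, 3L))

  # constant input -> constant window means; n anchors -> n-2 windows
  f2 <- make_anchored_indexes(rep(0.4, 10))
  w2 <- rolling_windows(f2$anchors, f2$index, 3)
  expect_equal(nrow(w2), 8L)
  expect_equal(w2$mean_index, rep(0.4, 8))

  # chromosome with fewer anchors than the window yields nothing
  f3 <- make_anchored_indexes(c(0.5, 0.5))
  expect_equal(nrow(rolling_windows(f3$anchors, f3$index, 3)), 0L)

  # undefined indexes are excluded, not imputed: remaining unigenes close up
  f4 <- make_anchored_indexes(c(1, 0.8, 0.6, 0.4))
  f4$index$index[2] <- NA
  w4 <- rolling_windows(f4$anchors, f4$index, 3)
  expect_equal(nrow(w4), 1L)
  expect_equal(w4$mean_index, mean(c(1, 0.6, 0.4)))

  # oracle + boundedness over random instances
  withr::with_seed(43, {
    for (i in 1:100) {
      n <- sample(1:30, 1); k <- sample(1:5, 1)
      idx <- round(stats::runif(n), 3)
      ff <- make_anchored_indexes(idx)
      ww <- rolling_windows(ff$anchors, ff$index, k)
      expect_equal(ww$mean_index, oracle_rolling_means(idx, k))
      if (nrow(ww)) {
        lo <- vapply(seq_len(nrow(ww)), function(j)
          min(idx[ww$win_start_rank[j]:ww$win_end_rank[j]]), 1)
        hi <- vapply(seq_len(nrow(ww)), function(j)
          max(idx[ww$win_start_rank[j]:ww$win_end_rank[j]]), 1)
        expect_true(all(ww$mean_index >= lo - 1e-12 &
                          ww$mean_index <= hi + 1e-12))
      }
    }
  })
})

test_that("call_regions merges maximal runs of hot windows", {
  idx <- c(0.1, 0.2, 1.0, 1.0, 0.9, 0.2, 0.1, 0.0)
  f <- make_anchored_indexes(idx)
  w <- rolling_windows(f$anchors, f$index, 3)
  expect_equal(round(w$mean_index, 3),
               c(0.433, 0.733, 0.967, 0.700, 0.400, 0.100))
  r <- call_regions(w, 0.60)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_unigenes, 5L)                 # anchors 2..6
  expect_equal(r$n_windows, 3L)
  expect_equal(r$span_start, f$anchors$start[2])
  expect_equal(r$span_end, f$anchors$end[6])
  expect_equal(r$peak_mean_index, w$mean_index[3])

  f0 <- make_anchored_indexes(rep(0, 8))
  expect_equal(nrow(call_regions(rolling_windows(f0$anchors, f0$index, 3))), 0L)

  f1 <- make_anchored_indexes(rep(1, 8))
  r1 <- call_regions(rolling_windows(f1$anchors, f1$index, 3))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_unigenes, 8L)
  expect_equal(c(r1$span_start, r1$span_end),
               c(min(f1$anchors$start), max(f1$anchors$end)))

  # run-length oracle on random window sequences
  withr::with_seed(44, {
    for (i in 1:100) {
      n <- sample(3:50, 1)
      idx <- round(stats::runif(n), 2)
      ff <- make_anchored_indexes(idx)
      ww <- rolling_windows(ff$anchors, ff$index, 3)
      rr <- call_regions(ww, 0.60)
      runs <- oracle_region_runs(ww$mean_index, 0.60)
      expect_equal(nrow(rr), length(runs))
      if (length(runs)) {
        expect_equal(rr$n_windows, lengths(runs), ignore_attr = TRUE)
        expect_equal(rr$peak_mean_index,
                     vapply(runs, function(ii) max(ww$mean_index[ii]), 1),
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("bsa_scan composes deterministically", {
  map <- build_genome_map(2, 12, 2, 1, 3e6, seed = 45)
  des <- cross_design("BC1", "chr02", 0.5)
  g <- simulate_backcross(map, des, 600, seed = 46)
  s <- apply_selection(g, map, des, seed = 47)
  cts <- simulate_bulk_counts(s, map, 200, 0.05, seed = 48)
  snps <- call_informative(counts_to_records(cts))
  hits <- generate_hit_tables(map, 0, 2, seed = 49)
  sc1 <- bsa_scan(snps, hits$forward, hits$reverse, map$genes)
  sc2 <- bsa_scan(snps, hits$forward, hits$reverse, map$genes)
  expect_identical(sc1, sc2)
  expect_s3_class(sc1$regions, "bsa_regions")
  expect_true(all(sc1$index$index >= 0 & sc1$index$index <= 1, na.rm = TRUE))
})
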