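# Variant-table parsing, informative-SNP calling, deletion footprint
# detection and the protein-effect arithmetic.

make_counts_fixture <- function() {
  map <- make_point_map(c(0.2, 0.5, 0.8), chrom_len = 1)
  surv <- cbind(rep(2L, 40), rep(c(2L, 1L), 20), rep(c(2L, 2L, 2L, 1L), 10))
  colnames(surv) <- map$markers$marker
  simulate_bulk_counts(surv, map, mean_coverage = 60, overdispersion = 0,
                       ase_bias = 1, seed = 31)
}

test_that("TSV and VCF encodings of the same variants parse identically", {
  cts <- make_counts_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_allele_counts(cts, tsv, comments = c("fixture"))
  write_vcf(cts, vcf)
  r1 <- read_variant_table(tsv, "tsv")
  r2 <- read_variant_table(vcf, "vcf")
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 3L)
  expect_identical(as.data.frame(r1), as.data.frame(counts_to_records(cts)))
})

test_that("read_variant_table validates its input", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("unigene\tpos\tref\talt\tsample\tref_count\talt_count", empty)
  expect_equal(nrow(read_variant_table(empty, "tsv")), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("unigene\tpos\tref\talt\tsample\tref_count\talt_count",
               "u1\t5\tA\tG\tXenR\t10\t0",
               "u1\t5\tA\tG\tFRA\tnot_a_number\t9",
               "u1\t5\tA\tG\tSelBC\t3\t7"), bad)
  expect_error(read_variant_table(bad, "tsv"), "line numbers.*3")

  incomplete <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("unigene\tpos\tref\talt\tsample\tref_count\talt_count",
               "u1\t5\tA\tG\tXenR\t10\t0"), incomplete)
  expect_error(read_variant_table(incomplete, "tsv"), "absent")
  expect_error(read_variant_table("no/such/file.tsv", "tsv"), "no such file")
})

test_that("call_informative applies the parental criteria and computes bulk frequency", {
  rec <- data.frame(
    unigene = c("u1", "u1", "u2", "u3"), pos = c(10L, 20L, 5L, 5L),
    ref = "A", alt = "G",
    #       informative   same-allele   low-coverage
    rp_ref = c(0L, 0L, 18L, 2L), rp_alt = c(20L, 25L, 1L, 1L),
    sp_ref = c(20L, 24L, 19L, 30L), sp_alt = c(0L, 1L, 0L, 0L),
    bulk_ref = c(10L, 2L, 15L, 20L), bulk_alt = c(30L, 38L, 15L, 20L),
    stringsAsFactors = FALSE)
  class(rec) <- c("variant_records", "data.frame")
  snps <- call_informative(rec, min_parent_cov = 10, parent_purity = 0.9,
                           min_bulk_cov = 20)
  expect_equal(nrow(snps), 2L)          # u2 (same allele) and u3 (depth) drop
  expect_equal(snps$res_allele, c("alt", "alt"))
  expect_equal(snps$bulk_freq, c(0.75, 0.95))
  expect_equal(snps$fixed, c(FALSE, FALSE))

  # bulk coverage below the minimum -> frequency undefined
  rec$bulk_ref[1] <- 5L; rec$bulk_alt[1] <- 5L
  expect_true(is.na(call_informative(rec)$bulk_freq[1]))
})

test_that("call_informative is symmetric under swapping the parents", {
  cts <- make_counts_fixture()
  rec <- counts_to_records(cts)
  swapped <- rec
  swapped[, c("rp_ref", "rp_alt")] <- rec[, c("sp_ref", "sp_alt")]
  swapped[, c("sp_ref", "sp_alt")] <- rec[, c("rp_ref", "rp_alt")]
  a <- call_informative(rec)
  b <- call_informative(swapped)
  expect_equal(nrow(a), nrow(b))
  expect_true(all(a$res_allele != b$res_allele))
  expect_equal(b$bulk_freq, 1 - a$bulk_freq)
})

test_that("is_fixed uses a strict threshold", {
  expect_true(is_fixed(0.96))
  expect_false(is_fixed(0.95))
  expect_true(is_fixed(1.0))
  expect_identical(is_fixed(NA_real_), NA)
  expect_error(is_fixed(1.2), "0,1")
})

test_that("deletion_scan finds the injected footprint and nothing else", {
  tr <- simulate_coverage_tracks(c(abc2 = 2000L), mean_coverage = 100,
                                 overdispersion = 0, seed = 32)
  tr <- inject_deletion(tr, "abc2", c(501L, 746L))   # 246 bp
  calls <- deletion_scan(tr$abc2$resistant, tr$abc2$susceptible,
                         min_len = 50, min_sus_cov = 10)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$length, 246L)
  expect_equal(c(calls$start, calls$end), c(501L, 746L))
  expect_equal(calls$res_max_cov, 0)

  flat <- simulate_coverage_tracks(c(u = 800L), 100, 0, seed = 33)
  expect_equal(nrow(deletion_scan(flat$u$resistant, flat$u$susceptible)), 0L)
  expect_error(deletion_scan(1:10, 1:9), "equal length")
})

test_that("deletion_scan agrees with the brute-force oracle on random tracks", {
  withr::with_seed(34, {
    for (i in 1:200) {
      n <- sample(20:500, 1)
      res <- stats::rpois(n, sample(c(0.2, 1, 5), 1))
      sus <- stats::rpois(n, 8)
      min_len <- sample(2:10, 1)
      min_sus <- sample(c(0, 5, 8), 1)
      max_res <- sample(0:1, 1)
      got <- deletion_scan(res, sus, min_len, min_sus, max_res)
      want <- oracle_deletion_scan(res, sus, min_len, min_sus, max_res)
      expect_equal(got[, c("start", "end")], want,
                   ignore_attr = TRUE)
      if (nrow(got) > 1) expect_true(all(diff(got$start) > 0) &&
                                       all(got$start[-1] > got$end[-nrow(got)]))
    }
  })
})

test_that("deletion_protein_effect does the codon arithmetic", {
  # in-frame 246-nt coding deletion removes 82 amino acids
  eff <- deletion_protein_effect(c(1L, 3000L), c(301L, 546L))
  expect_true(eff$in_frame)
  expect_equal(eff$aa_removed, 82L)
  expect_false(eff$premature_stop_possible)

  # 1-nt coding deletion shifts the frame
  fs <- deletion_protein_effect(c(1L, 3000L), c(100L, 100L))
  expect_false(fs$in_frame)
  expect_equal(fs$aa_removed, 0L)
  expect_true(fs$premature_stop_possible)

  # deleting a whole CDS of length 3k removes k residues
  whole <- deletion_protein_effect(c(201L, 200L + 3L * 57L), c(1L, 1000L))
  expect_equal(whole$aa_removed, 57L)

  # UTR-only deletion: zero effect, not an error
  utr <- deletion_protein_effect(c(500L, 1000L), c(10L, 100L))
  expect_equal(utr$coding_overlap, 0L)
  expect_equal(utr$aa_removed, 0L)
  expect_false(utr$premature_stop_possible)
})

test_that("bulk frequency at the locus is effectively fixed at deep coverage", {
  map <- build_genome_map(1, 5, 2, 1, 3e6, seed = 35)
  des <- cross_design("BC1", "chr01", 0.5)
  for (seed in 1:10) {
    g <- simulate_backcross(map, des, 400, seed = seed)
    s <- apply_selection(g, map, des, seed = seed + 100)
    cts <- simulate_bulk_counts(s, map, mean_coverage = 200,
                                overdispersion = 0.05, seed = seed + 200)
    snps <- call_informative(counts_to_records(cts))
    lm <- locus_marker(map, des)
    lu <- map$markers$unigene[map$markers$marker == lm]
    f <- snps$bulk_freq[snps$unigene == lu]
    expect_true(all(f > 0.95))
  }
})
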