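# Synthetic backcross populations, pooled allele counts, homology hit tables
# and deletion footprints.  Everything downstream of the wet lab is emulated
# here so that the mapping pipeline can be exercised end to end without any
# sequencing data.

SNP_SPACING_BP <- 100L  # physical spacing of SNPs within a unigene

#' Build a synthetic genome map with marker and unigene coordinates
#'
#' Lays out `unigenes_per_chrom` unigenes per chromosome on an even physical
#' grid (with random jitter inside each slot) and places `snps_per_unigene`
#' SNP markers at 100 bp spacing inside each unigene.  Genetic positions are
#' obtained from physical positions through a uniform Morgan/bp map, so both
#' coordinate systems are strictly increasing along a chromosome.
#'
#' @param n_chrom number of chromosomes (>= 1)
#' @param unigenes_per_chrom unigenes per chromosome (>= 1)
#' @param snps_per_unigene SNP markers per unigene (>= 1)
#' @param genetic_len genetic length of every chromosome, Morgans (> 0)
#' @param physical_len physical length of every chromosome, bp (> 0)
#' @param seed integer seed; the same seed always yields the same map
#' @return an object of class `genome_map`: a list with data frames
#'   `chromosomes` (chrom, genetic_len, physical_len), `markers`
#'   (marker, unigene, chrom, gpos, ppos, pos_in_unigene) sorted by physical
#'   position, and `genes` (gene, unigene, chrom, start, end, strand) giving
#'   the true reference-genome gene underlying each unigene.
#' @export
build_genome_map <- function(n_chrom, unigenes_per_chrom, snps_per_unigene,
                             genetic_len = 1, physical_len = 3e6, seed = 1L) {
  stop_if_not_scalar_count(n_chrom, "n_chrom")
  stop_if_not_scalar_count(unigenes_per_chrom, "unigenes_per_chrom")
  stop_if_not_scalar_count(snps_per_unigene, "snps_per_unigene")
  stop_if_not_positive(genetic_len, "genetic_len")
  stop_if_not_positive(physical_len, "physical_len")

  block <- (snps_per_unigene - 1L) * SNP_SPACING_BP + 1L
  slot <- floor(physical_len / unigenes_per_chrom)
  if (slot <= block + 1) {
    stop("physical_len too small for the requested unigene/SNP layout",
         call. = FALSE)
  }

  with_seed(seed, {
    markers <- vector("list", n_chrom)
    genes <- vector("list", n_chrom)
    for (ci in seq_len(n_chrom)) {
      chrom <- sprintf("chr%02d", ci)
      ug <- sprintf("ug_c%02d_%03d", ci, seq_len(unigenes_per_chrom))
      gene <- sprintf("BGN_c%02d_%03d", ci, seq_len(unigenes_per_chrom))
      offset <- floor(stats::runif(unigenes_per_chrom, 1, slot - block))
      start <- (seq_len(unigenes_per_chrom) - 1L) * slot + offset
      snp_off <- (seq_len(snps_per_unigene) - 1L) * SNP_SPACING_BP
      ppos <- rep(start, each = snps_per_unigene) +
        rep(snp_off, times = unigenes_per_chrom)
      markers[[ci]] <- data.frame(
        marker = sprintf("%s_s%02d", rep(ug, each = snps_per_unigene),
                         rep(seq_len(snps_per_unigene), unigenes_per_chrom)),
        unigene = rep(ug, each = snps_per_unigene),
        chrom = chrom,
        gpos = ppos / physical_len * genetic_len,
        ppos = as.integer(ppos),
        pos_in_unigene = rep(snp_off + 1L, times = unigenes_per_chrom),
        stringsAsFactors = FALSE
      )
      genes[[ci]] <- data.frame(
        gene = gene, unigene = ug, chrom = chrom,
        start = as.integer(start),
        end = as.integer(start + block + 199L),
        strand = "+", stringsAsFactors = FALSE
      )
    }
    out <- list(
      chromosomes = data.frame(
        chrom = sprintf("chr%02d", seq_len(n_chrom)),
        genetic_len = genetic_len, physical_len = physical_len,
        stringsAsFactors = FALSE
      ),
      markers = do.call(rbind, markers),
      genes = do.call(rbind, genes)
    )
    rownames(out$markers) <- NULL
    rownames(out$genes) <- NULL
    class(out) <- "genome_map"
    out
  })
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("genome_map: %d chromosome(s), %d unigenes, %d markers\n",
              nrow(x$chromosomes), nrow(x$genes), nrow(x$markers)))
  invisible(x)
}

#' Describe a genetic cross with a selected locus and genotype penetrance
#'
#' @param type `"BC1"` (F1 backcrossed to the resistant parent) or `"F1"`
#' @param locus_chrom chromosome id carrying the resistance locus
#' @param locus_gpos genetic position of the locus, Morgans
#' @param penetrance named survival probabilities for genotypes RR, RS, SS
#'   at the diagnostic dose.  The defaults encode a fully recessive trait
#'   whose homozygous-resistant baseline survival is 0.35.
#' @return an object of class `cross_design`
#' @export
cross_design <- function(type = c("BC1", "F1"), locus_chrom, locus_gpos,
                         penetrance = c(RR = 0.35, RS = 0, SS = 0)) {
  type <- match.arg(type)
  pen <- penetrance[c("RR", "RS", "SS")]
  if (any(is.na(pen))) stop("penetrance must name RR, RS and SS", call. = FALSE)
  stop_if_not_fraction(pen, "penetrance")
  structure(list(type = type, locus_chrom = locus_chrom,
                 locus_gpos = as.numeric(locus_gpos),
                 penetrance = pen),
            class = "cross_design")
}

# one meiotic gamete allele per marker for one chromosome; positions in Morgans
recombine_chrom <- function(gpos, chrom_len) {
  start <- stats::rbinom(1L, 1L, 0.5)        # which parental strand leads
  k <- stats::rpois(1L, chrom_len)           # Haldane: Poisson crossovers
  if (k == 0L) return(rep.int(start, length(gpos)))
  breaks <- sort(stats::runif(k, 0, chrom_len))
  (start + findInterval(gpos, breaks)) %% 2L
}

#' Simulate BC1 offspring genotypes across a genome map
#'
#' Each offspring receives one intact resistant haplotype from the recurrent
#' (resistant) parent and one recombinant F1 gamete.  Crossovers per
#' chromosome are Poisson with mean equal to the genetic length in Morgans
#' and breakpoints uniform (Haldane map, no interference), so before any
#' selection every marker is RR or RS with probability 1/2.
#'
#' @param map a `genome_map`
#' @param design a `cross_design`; its locus must lie on the map
#' @param n_offspring number of BC1 larvae to simulate (>= 1)
#' @param seed integer seed
#' @return integer matrix (offspring x marker) of resistant-allele dosage:
#'   2 = RR, 1 = RS.  Columns are named by marker id in map order.
#' @export
simulate_backcross <- function(map, design, n_offspring, seed = 1L) {
  stopifnot(inherits(map, "genome_map"), inherits(design, "cross_design"))
  stop_if_not_scalar_count(n_offspring, "n_offspring")
  ci <- match(design$locus_chrom, map$chromosomes$chrom)
  if (is.na(ci)) stop("resistance locus chromosome not on the map", call. = FALSE)
  clen <- map$chromosomes$genetic_len[ci]
  if (design$locus_gpos < 0 || design$locus_gpos > clen) {
    stop("resistance locus lies outside its chromosome's genetic length",
         call. = FALSE)
  }

  mk <- map$markers
  by_chrom <- split(seq_len(nrow(mk)), mk$chrom)
  with_seed(seed, {
    geno <- matrix(1L, nrow = n_offspring, ncol = nrow(mk),
                   dimnames = list(NULL, mk$marker))
    for (chrom in names(by_chrom)) {
      idx <- by_chrom[[chrom]]
      clen_c <- map$chromosomes$genetic_len[match(chrom, map$chromosomes$chrom)]
      gpos <- mk$gpos[idx]
      for (o in seq_len(n_offspring)) {
        # gamete allele 1 = resistant; dosage = 1 (recurrent haplotype) + gamete
        geno[o, idx] <- 1L + recombine_chrom(gpos, clen_c)
      }
    }
    geno
  })
}

#' Marker nearest to the declared resistance locus
#'
#' Ties are broken toward the lower physical coordinate.
#' @param map a `genome_map`
#' @param design a `cross_design`
#' @return the marker id (character scalar)
#' @export
locus_marker <- function(map, design) {
  mk <- map$markers[map$markers$chrom == design$locus_chrom, , drop = FALSE]
  if (nrow(mk) == 0L) stop("no markers on the locus chromosome", call. = FALSE)
  d <- abs(mk$gpos - design$locus_gpos)
  cand <- which(d == min(d))
  mk$marker[cand[which.min(mk$ppos[cand])]]
}

#' Apply diagnostic-dose selection to simulated offspring
#'
#' Each offspring survives with probability equal to the penetrance of its
#' genotype at the marker nearest the resistance locus.  An empty survivor
#' set is reported via a warning of class `bsascan_no_survivors` and an
#' empty matrix, never an error.
#'
#' @param genotypes matrix from [simulate_backcross()]
#' @param map the `genome_map` used to generate `genotypes`
#' @param design a `cross_design` with the penetrance model
#' @param seed integer seed
#' @return the surviving rows of `genotypes`
#' @export
apply_selection <- function(genotypes, map, design, seed = 1L) {
  stopifnot(is.matrix(genotypes), inherits(design, "cross_design"))
  lm <- locus_marker(map, design)
  dosage <- genotypes[, lm]
  surv_p <- ifelse(dosage == 2L, design$penetrance[["RR"]],
                   design$penetrance[["RS"]])
  with_seed(seed, {
    alive <- stats::runif(nrow(genotypes)) < surv_p
    out <- genotypes[alive, , drop = FALSE]
    if (nrow(out) == 0L) {
      warning(structure(
        class = c("bsascan_no_survivors", "warning", "condition"),
        list(message = "selection left no survivors", call = sys.call(-1))))
    }
    out
  })
}

#' Simulate pooled allele read counts for the three sequenced samples
#'
#' Per-marker coverage is negative-binomial with the given mean and
#' dispersion (Poisson when `overdispersion = 0`), drawn independently for
#' the resistant parent, the susceptible parent, and the selected bulk.
#' Resistant-allele reads in the bulk are binomial with success probability
#' equal to the survivor-pool allele frequency, optionally distorted by an
#' allele-specific expression factor `b` as `p' = b p / (b p + 1 - p)`.
#' Parents are homozygous, so their reads all carry their own allele.
#'
#' @param survivors genotype dosage matrix of the selected pool
#' @param map the `genome_map`
#' @param mean_coverage mean read depth per marker (> 0); the default mirrors
#'   the ~750x transcriptome coverage regime the design targets
#' @param overdispersion negative-binomial dispersion (variance =
#'   mu + overdispersion * mu^2); 0 = Poisson
#' @param ase_bias allele-specific expression factor `b` in (0, Inf); 1 is
#'   unbiased, 0 silences the resistant allele entirely
#' @param seed integer seed
#' @return object of class `bulk_counts`: data frame with one row per marker
#'   (marker, unigene, chrom, pos_in_unigene, ref, alt, res_is_alt, pool
#'   frequency, and `<sample>_res` / `<sample>_sus` read counts for samples
#'   xenr, fra and bulk)
#' @export
simulate_bulk_counts <- function(survivors, map, mean_coverage = 750,
                                 overdispersion = 0.05, ase_bias = 1,
                                 seed = 1L) {
  stop_if_not_positive(mean_coverage, "mean_coverage")
  if (!is.numeric(ase_bias) || length(ase_bias) != 1L || ase_bias < 0) {
    stop("`ase_bias` must be a single number >= 0", call. = FALSE)
  }
  if (overdispersion < 0) stop("`overdispersion` must be >= 0", call. = FALSE)
  if (nrow(survivors) == 0L) stop("no survivors to pool", call. = FALSE)

  mk <- map$markers
  stopifnot(identical(colnames(survivors), mk$marker))
  p <- colMeans(survivors) / 2          # pool resistant-allele frequency
  pb <- ase_bias * p / (ase_bias * p + (1 - p))
  pb[p == 1] <- if (ase_bias > 0) 1 else 0
  n <- nrow(mk)

  rcov <- function(n) {
    if (overdispersion == 0) stats::rpois(n, mean_coverage)
    else stats::rnbinom(n, mu = mean_coverage, size = 1 / overdispersion)
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    res_is_alt <- stats::runif(n) < 0.5
    cov_x <- rcov(n); cov_f <- rcov(n); cov_b <- rcov(n)
    bulk_res <- stats::rbinom(n, cov_b, pb)
    out <- data.frame(
      marker = mk$marker, unigene = mk$unigene, chrom = mk$chrom,
      pos_in_unigene = mk$pos_in_unigene,
      ref = ref, alt = unname(alt), res_is_alt = res_is_alt,
      pool_freq = p,
      xenr_res = cov_x, xenr_sus = 0L,
      fra_res = 0L, fra_sus = cov_f,
      bulk_res = bulk_res, bulk_sus = cov_b - bulk_res,
      stringsAsFactors = FALSE
    )
    class(out) <- c("bulk_counts", "data.frame")
    out
  })
}

#' Simulate per-position coverage tracks for a set of unigenes
#'
#' @param lengths named integer vector: unigene id -> transcript length (bp)
#' @param mean_coverage mean depth per position
#' @param overdispersion negative-binomial dispersion; 0 = Poisson
#' @param seed integer seed
#' @return named list; each element is `list(resistant =, susceptible =)`
#'   numeric vectors of per-position depth
#' @export
simulate_coverage_tracks <- function(lengths, mean_coverage = 750,
                                     overdispersion = 0.05, seed = 1L) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  rcov <- function(n) {
    if (overdispersion == 0) stats::rpois(n, mean_coverage)
    else stats::rnbinom(n, mu = mean_coverage, size = 1 / overdispersion)
  }
  with_seed(seed, {
    out <- lapply(lengths, function(L) {
      list(resistant = as.numeric(rcov(L)), susceptible = as.numeric(rcov(L)))
    })
    names(out) <- names(lengths)
    out
  })
}

#' Zero out resistant-bulk coverage over a deletion interval
#'
#' Emulates a homozygous genomic deletion in the resistant material: no read
#' from the selected bulk maps inside the interval, while the susceptible
#' track is untouched.
#'
#' @param tracks list from [simulate_coverage_tracks()]
#' @param unigene unigene id present in `tracks`
#' @param interval integer `c(start, end)` (1-based inclusive, transcript
#'   coordinates) or `NULL`/zero-length for no change
#' @return the modified track list
#' @export
inject_deletion <- function(tracks, unigene, interval) {
  if (is.null(interval) || length(interval) == 0L) return(tracks)
  if (!unigene %in% names(tracks)) stop("unknown unigene", call. = FALSE)
  L <- length(tracks[[unigene]]$resistant)
  start <- interval[[1]]; end <- interval[[2]]
  if (start < 1 || end > L || start > end) {
    stop("deletion interval outside the unigene", call. = FALSE)
  }
  tracks[[unigene]]$resistant[start:end] <- 0
  tracks
}

#' Generate a pair of directional homology hit tables
#'
#' Emulates tabular output of a bidirectional homology search between the
#' unigene set and the reference proteome.  Every unigene that is not
#' dropped gets a top-scoring hit to its true reference gene (and vice
#' versa), plus `decoy_paralogs` hits to other genes with strictly lower
#' bitscores, so reciprocal-best-hit filtering recovers the true map.
#'
#' @param map a `genome_map`
#' @param missing_fraction fraction of unigenes with no hits at all, in [0,1)
#' @param decoy_paralogs decoy lower-scoring hits per query (>= 0)
#' @param seed integer seed
#' @return `list(forward =, reverse =)`; each a data frame with columns
#'   qseqid, sseqid, pident, length, evalue, bitscore
#' @export
generate_hit_tables <- function(map, missing_fraction = 0, decoy_paralogs = 0,
                                seed = 1L) {
  stop_if_not_fraction(missing_fraction, "missing_fraction", open_upper = TRUE)
  if (decoy_paralogs < 0) stop("`decoy_paralogs` must be >= 0", call. = FALSE)
  genes <- map$genes
  n <- nrow(genes)
  with_seed(seed, {
    keep <- stats::runif(n) >= missing_fraction
    mk_rows <- function(q, s, top_score, n_decoy, decoy_pool) {
      score <- c(top_score, top_score * stats::runif(n_decoy, 0.3, 0.8))
      subj <- c(s, if (n_decoy > 0) sample(decoy_pool, n_decoy))
      data.frame(qseqid = q, sseqid = subj,
                 pident = round(stats::runif(1 + n_decoy, 75, 99), 2),
                 length = as.integer(stats::runif(1 + n_decoy, 100, 900)),
                 evalue = signif(10^-(score / 30), 3),
                 bitscore = round(score, 1), stringsAsFactors = FALSE)
    }
    fwd <- vector("list", n); rev <- vector("list", n)
    for (i in seq_len(n)) {
      if (!keep[i]) next
      top <- stats::runif(1, 300, 1000)
      nd <- min(decoy_paralogs, n - 1L)
      fwd[[i]] <- mk_rows(genes$unigene[i], genes$gene[i], top, nd,
                          genes$gene[-i])
      rev[[i]] <- mk_rows(genes$gene[i], genes$unigene[i], top, nd,
                          genes$unigene[-i])
    }
    list(forward = do.call(rbind, fwd[keep]),
         reverse = do.call(rbind, rev[keep]))
  })
}
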