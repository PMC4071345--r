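# Pipeline driver: simulate -> variant calling -> genome scan -> report,
# plus the command-line entry point with subcommands.

#' Default pipeline configuration
#'
#' The simulation block encodes the stated mapping design: a BC1 to the
#' resistant parent selected at one fully recessive locus (RR survival
#' 0.35, all other genotypes killed at the diagnostic dose), five
#' chromosomes of 40 anchored unigenes with 3 SNPs each, and pooled
#' sequencing at 200x mean marker coverage.
#'
#' @param seed integer seed for every random stage
#' @param out_dir output directory
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L, out_dir = "bsascan_out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(
      n_chrom = 5L, unigenes_per_chrom = 40L, snps_per_unigene = 3L,
      genetic_len = 1, physical_len = 3e6,
      locus_chrom = "chr03", locus_gpos = 0.5,
      penetrance = c(RR = 0.35, RS = 0, SS = 0),
      n_offspring = 2000L, mean_coverage = 200, overdispersion = 0.05,
      ase_bias = 1, missing_fraction = 0, decoy_paralogs = 2L
    ),
    variants = list(min_parent_cov = 10, parent_purity = 0.9,
                    min_bulk_cov = 20, fix_threshold = 0.95),
    scan = list(window_size = 3L, region_threshold = 0.60, min_snps = 1L)
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value.
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @return configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), user)
  cfg$simulate$penetrance <- unlist(cfg$simulate$penetrance)
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulate -> variants -> scan -> report pipeline
#'
#' Writes all intermediate tables (allele counts as TSV and VCF, homology
#' hit tables, gene positions, informative SNPs, unigene index, windows,
#' regions), a genome-scan plot, a run log and a human-readable summary
#' into `config$out_dir`.  Every table carries its parameters and seed as
#' leading `#` comment lines; identical configurations produce identical
#' bundles.
#'
#' @param config configuration list from [default_config()] or
#'   [load_config()]
#' @return invisibly, a list with the `bsa_scan` result, the locus unigene
#'   id, and the paths of all written files
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- utils::modifyList(default_config(), config)
  cfg$simulate$penetrance <- unlist(cfg$simulate$penetrance)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$out_dir, f)
  seed <- cfg$seed
  hdr <- c(sprintf("bsascan run, seed=%d", seed),
           sprintf("params: %s", jsonlite::toJSON(cfg[c("simulate", "variants", "scan")],
                                                  auto_unbox = TRUE)))

  sim <- cfg$simulate
  stage_sim <- run_stage("simulate", {
    map <- build_genome_map(sim$n_chrom, sim$unigenes_per_chrom,
                            sim$snps_per_unigene, sim$genetic_len,
                            sim$physical_len, seed = derive_seed(seed, "map"))
    design <- cross_design("BC1", sim$locus_chrom, sim$locus_gpos,
                           penetrance = sim$penetrance)
    geno <- simulate_backcross(map, design, sim$n_offspring,
                               seed = derive_seed(seed, "meiosis"))
    surv <- apply_selection(geno, map, design,
                            seed = derive_seed(seed, "selection"))
    if (nrow(surv) == 0L) stop("selection left no survivors")
    counts <- simulate_bulk_counts(surv, map, sim$mean_coverage,
                                   sim$overdispersion, sim$ase_bias,
                                   seed = derive_seed(seed, "counts"))
    hits <- generate_hit_tables(map, sim$missing_fraction,
                                sim$decoy_paralogs,
                                seed = derive_seed(seed, "hits"))
    write_allele_counts(counts, p("allele_counts.tsv"), comments = hdr)
    write_vcf(counts, p("variants.vcf"))
    write_hit_tables(hits, p("hits_fwd.tsv"), p("hits_rev.tsv"))
    write_gene_positions(map$genes, p("gene_positions.tsv"))
    list(map = map, design = design,
         locus_unigene = map$markers$unigene[
           match(locus_marker(map, design), map$markers$marker)])
  })

  vp <- cfg$variants
  snps <- run_stage("variants", {
    rec <- read_variant_table(p("allele_counts.tsv"), dialect = "tsv")
    s <- call_informative(rec, vp$min_parent_cov, vp$parent_purity,
                          vp$min_bulk_cov, vp$fix_threshold)
    write_informative_snps(s, p("informative_snps.tsv"), comments = hdr)
    s
  })

  sp <- cfg$scan
  scan <- run_stage("scan", {
    sc <- bsa_scan(snps, read_hit_table(p("hits_fwd.tsv")),
                   read_hit_table(p("hits_rev.tsv")),
                   read_gene_positions(p("gene_positions.tsv")),
                   window_size = sp$window_size,
                   region_threshold = sp$region_threshold,
                   min_snps = sp$min_snps)
    write_tsv_commented(sc$index, p("unigene_index.tsv"), hdr)
    write_tsv_commented(as.data.frame(sc$windows), p("windows.tsv"), hdr)
    write_tsv_commented(as.data.frame(sc$regions), p("regions.tsv"), hdr)
    if (nrow(sc$windows) > 0) {
      plot_bsa_index(sc$windows, threshold = sp$region_threshold,
                     path = p("bsa_index.png"))
    }
    sc
  })

  run_stage("report", {
    log_lines <- c(hdr,
                   sprintf("R version: %s", R.version.string),
                   sprintf("bsascan version: %s",
                           as.character(utils::packageVersion("bsascan"))),
                   sprintf("date: %s", format(Sys.time(), "%Y-%m-%d")))
    writeLines(log_lines, p("run_log.txt"))
    reg <- scan$regions
    summ <- c(sprintf("informative SNPs: %d", nrow(snps)),
              sprintf("unigenes with a defined index: %d",
                      sum(!is.na(scan$index$index))),
              sprintf("candidate regions (window mean > %.2f): %d",
                      sp$region_threshold, nrow(reg)),
              sprintf("simulated resistance unigene: %s",
                      stage_sim$locus_unigene))
    if (nrow(reg) > 0) {
      top <- top_region(reg)
      summ <- c(summ, sprintf(
        "top region: %s:%d-%d (%d unigenes, peak window mean %.3f)",
        top$chrom, top$span_start, top$span_end, top$n_unigenes,
        top$peak_mean_index))
    }
    writeLines(summ, p("summary.txt"))
  })

  invisible(list(scan = scan, locus_unigene = stage_sim$locus_unigene,
                 config = cfg,
                 files = list.files(cfg$out_dir, full.names = TRUE)))
}

#' Command-line entry point
#'
#' Subcommands: `pipeline` (full run from a config), `simulate` (write
#' synthetic input tables), `scan` (BSA scan from existing tables),
#' `filter` (transcriptome filter), `genetics` (mortality consistency),
#' `binding` (fit or dissect).  Run with `--help` after a subcommand for
#' its flags.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   actual command line)
#' @return exit status, invisibly (0 on success)
#' @export
bsascan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: bsascan <pipeline|simulate|scan|filter|genetics|binding> [options]")
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(sub,
      pipeline = cli_pipeline(rest),
      simulate = cli_simulate(rest),
      scan = cli_scan(rest),
      filter = cli_filter(rest),
      genetics = cli_genetics(rest),
      binding = cli_binding(rest),
      { message("unknown subcommand: ", sub); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}

cli_pipeline <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "bsascan_out")
  )), args = args)
  cfg <- if (is.null(opts$config)) default_config() else load_config(opts$config)
  cfg$seed <- opts$seed
  cfg$out_dir <- opts$out
  res <- run_pipeline(cfg)
  message("wrote ", length(res$files), " files to ", cfg$out_dir)
  0L
}

cli_simulate <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--n-offspring", type = "integer", default = 2000L,
                          dest = "n_offspring"),
    optparse::make_option("--coverage", type = "double", default = 200),
    optparse::make_option("--penetrance", type = "character",
                          default = "0.35,0,0",
                          help = "RR,RS,SS survival probabilities"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "bsascan_out")
  )), args = args)
  pen <- as.numeric(strsplit(opts$penetrance, ",")[[1]])
  cfg <- default_config(seed = opts$seed, out_dir = opts$out)
  cfg$simulate$n_offspring <- opts$n_offspring
  cfg$simulate$mean_coverage <- opts$coverage
  cfg$simulate$penetrance <- c(RR = pen[1], RS = pen[2], SS = pen[3])
  run_pipeline(cfg)
  0L
}

cli_scan <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--snps", type = "character"),
    optparse::make_option("--fwd", type = "character"),
    optparse::make_option("--rev", type = "character"),
    optparse::make_option("--genes", type = "character"),
    optparse::make_option("--window-size", type = "integer", default = 3L,
                          dest = "window_size"),
    optparse::make_option("--region-threshold", type = "double",
                          default = 0.60, dest = "region_threshold"),
    optparse::make_option("--min-snps", type = "integer", default = 1L,
                          dest = "min_snps"),
    optparse::make_option("--out", type = "character", default = ".")
  )), args = args)
  sc <- bsa_scan(opts$snps, opts$fwd, opts$rev, opts$genes,
                 window_size = opts$window_size,
                 region_threshold = opts$region_threshold,
                 min_snps = opts$min_snps)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  write_tsv_commented(sc$index, file.path(opts$out, "unigene_index.tsv"))
  write_tsv_commented(as.data.frame(sc$windows),
                      file.path(opts$out, "windows.tsv"))
  write_tsv_commented(as.data.frame(sc$regions),
                      file.path(opts$out, "regions.tsv"))
  print(sc)
  0L
}

cli_filter <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--annotations", type = "character"),
    optparse::make_option("--total-mapped", type = "double",
                          dest = "total_mapped"),
    optparse::make_option("--out", type = "character", default = "kept.tsv")
  )), args = args)
  ann <- read_tsv_commented(opts$annotations)
  kept <- filter_unigenes(ann, opts$total_mapped)
  write_tsv_commented(kept, opts$out)
  message(nrow(kept), " of ", nrow(ann), " unigenes kept")
  0L
}

cli_genetics <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--cross", type = "character", default = "BC1"),
    optparse::make_option("--dead", type = "integer"),
    optparse::make_option("--n", type = "integer"),
    optparse::make_option("--penetrance", type = "character",
                          default = "0.35,0,0")
  )), args = args)
  pen <- as.numeric(strsplit(opts$penetrance, ",")[[1]])
  pen <- c(RR = pen[1], RS = pen[2], SS = pen[3])
  exp_m <- expected_mortality(genotype_distribution(opts$cross), pen)
  cat(sprintf("cross %s: expected mortality %.4f\n", opts$cross, exp_m))
  if (!is.null(opts$dead) && !is.null(opts$n)) {
    mc <- mortality_consistency(opts$dead, opts$n, exp_m)
    cat(sprintf("observed %d/%d = %.3f, exact binomial p = %.4f, 95%% CI [%.3f, %.3f]\n",
                opts$dead, opts$n, mc$observed, mc$p_value, mc$ci[1], mc$ci[2]))
  }
  0L
}

cli_binding <- function(args) {
  if (length(args) == 0L) {
    message("usage: bsascan binding <fit|dissect> [options]")
    return(1L)
  }
  mode <- args[1]
  rest <- args[-1]
  if (mode == "fit") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--curve", type = "character"),
      optparse::make_option("--hot", type = "double", default = 1)
    )), args = rest)
    fit <- fit_homologous_competition(read_binding_curve(opts$curve),
                                      hot = opts$hot)
    print(fit)
    return(if (fit$converged) 0L else 1L)
  }
  if (mode == "dissect") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
      optparse::make_option("--total", type = "double"),
      optparse::make_option("--nonspecific", type = "double"),
      optparse::make_option("--irreversible", type = "double")
    )), args = rest)
    d <- dissect_binding(opts$total, opts$nonspecific, opts$irreversible)
    cat(sprintf("specific %.4g, reversible %.4g, irreversible %.4g\n",
                d$specific, d$reversible, d$irreversible))
    return(0L)
  }
  message("unknown binding mode: ", mode)
  1L
}
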