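# Monogenic recessive penetrance model for the resistance locus: expected
# genotype distributions and mortalities under each cross, and exact
# binomial consistency checks of observed bulk mortalities.

#' Genotype distribution at the resistance locus for a given cross
#'
#' Assumes a single autosomal biallelic locus.  `BC1` is the F1 backcrossed
#' to the resistant (RR) parent.
#'
#' @param cross one of `"F1"`, `"BC1"`, `"parental-R"`, `"parental-S"`
#' @return named numeric vector of genotype probabilities over RR, RS, SS
#' @export
genotype_distribution <- function(cross = c("BC1", "F1", "parental-R",
                                            "parental-S")) {
  cross <- match.arg(cross)
  switch(cross,
         "F1" = c(RR = 0, RS = 1, SS = 0),
         "BC1" = c(RR = 0.5, RS = 0.5, SS = 0),
         "parental-R" = c(RR = 1, RS = 0, SS = 0),
         "parental-S" = c(RR = 0, RS = 0, SS = 1))
}

#' Expected mortality of a cross under a penetrance model
#'
#' Computes `1 - sum_g P(g) * survival(g)`.  With the default recessive
#' penetrance (RR survival 0.35, all others 0) the expectation is 0.65 for
#' the resistant parental and 0.825 for a BC1 family.
#'
#' @param dist genotype distribution (see [genotype_distribution()])
#' @param penetrance named survival probabilities for RR, RS, SS
#' @return expected mortality fraction in \[0,1\]
#' @export
expected_mortality <- function(dist, penetrance = c(RR = 0.35, RS = 0, SS = 0)) {
  g <- c("RR", "RS", "SS")
  d <- dist[g]; s <- penetrance[g]
  if (any(is.na(d)) || any(is.na(s))) {
    stop("distribution and penetrance must name RR, RS and SS", call. = FALSE)
  }
  stop_if_not_fraction(s, "penetrance")
  if (abs(sum(d) - 1) > 1e-8) stop("distribution must sum to 1", call. = FALSE)
  1 - sum(d * s)
}

#' Expected resistant-parent genome fraction at loci unlinked to selection
#'
#' In a BC1 to the resistant parent every offspring carries one full
#' resistant haplotype (dosage 1/2) plus an F1 gamete contributing the
#' resistant allele with probability 1/2, so the expected resistant-allele
#' fraction is (1 + 0.5) / 2 = 0.75 at any locus unlinked to the selected
#' one.  An F1 individual carries exactly half of each parental genome.
#'
#' @param cross `"BC1"` or `"F1"`
#' @return expected resistant-genome fraction
#' @export
expected_background_fraction <- function(cross = c("BC1", "F1")) {
  cross <- match.arg(cross)
  switch(cross, "BC1" = 0.75, "F1" = 0.5)
}

#' Exact binomial consistency check of an observed mortality
#'
#' Two-sided exact binomial test of the observed death count against an
#' expected mortality, with the Clopper-Pearson 95% interval of the
#' observed proportion.  Used to ask whether bulk mortalities are
#' compatible with a single-major-locus model.
#'
#' @param dead observed number of dead larvae (0 <= dead <= n)
#' @param n family size (> 0)
#' @param expected expected mortality fraction
#' @param conf_level confidence level of the interval
#' @return list with `p_value`, `ci` (length-2 vector), `observed` fraction
#'   and `expected`
#' @export
mortality_consistency <- function(dead, n, expected, conf_level = 0.95) {
  stop_if_not_scalar_count(n, "n", min = 1L)
  stop_if_not_scalar_count(dead, "dead", min = 0L)
  if (dead > n) stop("`dead` cannot exceed `n`", call. = FALSE)
  stop_if_not_fraction(expected, "expected")
  bt <- stats::binom.test(dead, n, p = expected, alternative = "two.sided",
                          conf.level = conf_level)
  list(p_value = bt$p.value,
       ci = as.numeric(bt$conf.int),
       observed = dead / n,
       expected = expected)
}
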