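---
title: "Methods: asymmetric single-bulk BSA from pooled RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetric single-bulk BSA from pooled RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The mapping problem

`bsascan` maps a fully recessive insecticide-resistance locus in a species
without a reference genome, from three pooled RNA-seq samples: the
resistant parental colony, the susceptible parental colony, and a single
bulk of backcross survivors ("selected bulk"). The design is *asymmetric*
bulk segregant analysis: because susceptible segregants cannot be scored
reliably after a lethal diagnostic dose, only the resistant extreme is
sequenced, and linkage is detected as deviation of the bulk allele
frequency from its neutral backcross expectation rather than as a
difference between two bulks.

## Genetic model

One autosomal biallelic locus with alleles R (resistant) and S. The cross
is F1 (RS) x resistant parent (RR), so every BC1 marker genotype is RR or
RS with probability 1/2 before selection. Survival at the diagnostic dose
is a genotype penetrance vector; the default `{RR: 0.35, RS: 0, SS: 0}`
encodes complete recessivity with a 65% baseline mortality of the
homozygous-resistant colony itself, giving an expected BC1 mortality of
`1 - 0.5*0.35 = 0.825`. `mortality_consistency()` checks observed family
mortalities against this expectation with an exact binomial test
(`stats::binom.test`); the exact test was chosen over a normal
approximation because family sizes are unstated and may be small.

Selection drives the R-allele frequency among survivors to 1 at the locus,
to `1 - r/2` at a marker with recombination fraction `r` to the locus, and
leaves an expected `(1 + 0.5)/2 = 0.75` resistant-genome background at
unlinked loci.

## Meiosis simulator

`simulate_backcross()` draws, per chromosome and gamete, a
Poisson-distributed crossover count with mean equal to the genetic length
in Morgans and uniform breakpoints — the Haldane model, no interference.
This choice is standard and analytically checkable: the recombinant
fraction between two markers `d` Morgans apart is `0.5(1 - e^{-2d})`,
which the test suite verifies by Monte Carlo. Selection
(`apply_selection()`) uses the marker nearest the declared locus position,
ties broken toward the lower physical coordinate, because the locus need
not coincide with a marker.

## Read-count model

`simulate_bulk_counts()` draws per-marker coverage from a negative
binomial parameterised by mean and dispersion (`dispersion = 0`
degenerates to Poisson); RNA-seq coverage is overdispersed, and the
default mean of 750 reflects the deep (~760x) transcriptome coverage
regime of the motivating experiment, while the locus-recovery scenario
uses 200x. Resistant-allele reads are binomial at the pool frequency,
optionally distorted by an allele-specific-expression factor `b` as
`p' = bp / (bp + 1 - p)` (`b = 1` unbiased). This models the caveat that
cDNA pools need not sample the two alleles of a gene evenly; the genomic
smoothing below is the analysis-side answer to the same caveat.

What the generator does *not* emulate: sequencing error in the parental
samples (parents are pure), mapping bias, assembly artifacts, and
multi-family pedigree structure. A green locus-recovery test therefore
establishes that the statistical chain works under the stated genetic
model, not that any particular wet-lab dataset would behave as cleanly.

## Informative SNPs and the fixation index

A variant is *informative* when both parents are covered (default depth
>= 10), near-homozygous (major-allele frequency >= 0.9) and fixed for
opposite alleles. These three defaults are package choices — the source
experiment does not print its criteria — and are configuration knobs. The
bulk frequency of the resistant-parent allele is computed when bulk depth
>= 20, otherwise flagged undefined.

The per-unigene **fixation index** is the fraction of informative SNPs
whose resistant-parent allele exceeds frequency 0.95 in the bulk, out of
all informative SNPs in that unigene. Both thresholds in the pipeline
(0.95 fixation, 0.60 region calling) are *strict* comparisons. Indels are
excluded: the index is defined over SNPs. Unigenes with no
frequency-defined SNP get an undefined index and are excluded from
windows rather than imputed as 0 — absence of evidence is not evidence of
non-fixation.

## Anchoring, windows and regions

Unigenes are placed on a related reference genome through reciprocal best
hits between two directional homology hit tables; ties are broken by
bitscore, then e-value, then lexicographic subject id, so results are
reproducible. Windows average the index over three *consecutive anchored
orthologs* (rank space, stride 1), not fixed-bp bins; candidate regions
are maximal runs of rank-consecutive windows with mean strictly above
0.60, reported with their genomic span and member-unigene count. The 0.60
threshold is applied to window means only, matching the rolling-window
definition of the scan; single-unigene indexes are reported but not
thresholded. No significance envelope is computed — the method uses a
fixed threshold by design.

When one "top" region must be named (run summaries, parameter-recovery
tests) regions are ranked by peak window mean, then by run length, then
by member count: a sustained signal outranks an isolated spike of equal
height. This ranking is a package choice.

## Deletion footprint

A homozygous genomic deletion in the resistant material appears in
transcript space as an interval with zero selected-bulk coverage despite
high susceptible coverage. `deletion_scan()` reports maximal intervals of
length >= `min_len` where resistant coverage never exceeds `max_res_cov`
(default 0) and susceptible mean coverage is >= `min_sus_cov`.
`deletion_protein_effect()` intersects a deletion with the CDS: a coding
overlap divisible by 3 removes `overlap/3` residues in frame (246 nt ->
82 aa); any other overlap is a frameshift with a possible premature stop.
The codon arithmetic assumes the deletion respects codon phase when
declared in frame; sub-codon junction effects are out of scope.

## Transcriptome filter

`filter_unigenes()` keeps a unigene if it passes *any one* of: has a CDS,
has a homology match, expression strictly above 0.25 RPKM, or length
strictly above 500 bp. Which library's mapped-read total defines the RPKM
denominator is an explicit argument, since the convention is not fixed.
`cluster_representative()` picks the longest unigene per cluster, ties to
the smallest id.

## Binding model

Homologous competition with a trace of labeled toxin (H, 1 nM) and
increasing unlabeled toxin (C), one site class, equal hot/cold affinity,
no ligand depletion:

B(C) = R_t · H / (K_d + H + C) + NS · H

This is the textbook reduction that classical binding-analysis software
converges to in this regime; a ligand-depletion (quadratic) variant is a
possible extension, not implemented. Fitting is nonlinear least squares
(`stats::nls`, port algorithm, K_d > 0, R_t >= 0, NS >= 0) with
proportional-error weights `1/B̂²` applied by iterated reweighting —
counting instruments show proportional error — and asymptotic standard
errors from the final Jacobian. Starting values come from the curve shape
(plateau -> NS, half-displacement concentration -> K_d + H, amplitude ->
R_t), and a curve with no displacement at all is flagged degenerate
rather than fitted. For simulation-recovery tests the truth is the
susceptible-strain estimate (K_d = 14 nM, R_t = 5.9 pmol/mg) with a
nonspecific slope of 0.02 — the published table reports no NS value, so a
small realistic contribution was fixed once, before any fitting, and
never revisited.

The three-sample dissection computes specific = total − nonspecific,
irreversible = delayed-competitor sample − nonspecific, reversible =
specific − irreversible. Negative components (possible with noisy inputs)
are clamped to zero with a warning in a way that preserves
reversible + irreversible = specific exactly.

## Numerical and degenerate-input choices

- All randomness flows from one integer seed per operation
  (`withr::with_seed`); no global RNG state is disturbed. Pipeline stages
  derive child seeds from the run seed and a stage label.
- Selection that kills every offspring raises a classed warning
  (`bsascan_no_survivors`) and returns an empty matrix; the pipeline
  converts it into a labeled stage failure.
- Rolling means use a cumulative-sum formulation; tests compare with a
  looped oracle at floating-point tolerance.
- Multiallelic variant records are dropped, not split.
- Coordinates are 1-based inclusive throughout transcript space.

## Known limitations

- Single-bulk design only: no two-bulk Δ-index statistic.
- No synteny-aware correction: anchoring assumes the reference gene order
  is informative, which chromosomal rearrangements can violate locally.
- Penetrance is treated as constant at the diagnostic dose.
- The binding module fits one site class; heterologous competition and
  between-strain component statistics are out of scope.
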