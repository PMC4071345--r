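Package: bsascan
Title: Asymmetric Bulk Segregant Analysis of Pooled RNA-Seq for Recessive
    Resistance Mapping
Version: 0.1.0
Authors@R:
    person("BSA", "Maintainers", email = "maintainers@bsascan.org",
           role = c("aut", "cre"))
Description: Maps a recessive insecticide-resistance locus from pooled
    RNA-seq allele counts using a single selected backcross bulk.  Provides
    a backcross meiosis simulator (Haldane model) with genotype-dependent
    survival, a per-unigene allele-fixation index, reciprocal-best-hit
    ortholog anchoring onto a reference genome, rolling-window candidate
    region calling, zero-coverage deletion detection with protein-effect
    arithmetic, transcriptome filtering rules (RPKM, length, CDS and
    homology criteria), and nonlinear fitting of homologous-competition
    radioligand binding curves with dissection of specific binding into
    reversible and irreversible components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    withr,
    jsonlite,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
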