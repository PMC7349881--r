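Package: herdassess
Title: Conservation Assessment of Livestock Populations from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic conservation assessment for small livestock populations
    genotyped on medium-density SNP arrays. Reads PLINK PED/MAP and BED/BIM/FAM
    files, applies sequential quality-control filters with a full accounting
    report, computes within-population diversity (polymorphism proportion,
    observed and expected heterozygosity, homozygosity-excess inbreeding),
    builds the VanRaden genomic relationship matrix with diagonal-derived
    inbreeding and identifies family groups, detects runs of homozygosity by a
    consecutive-SNP scan and derives ROH-based inbreeding at genome, chromosome
    and length-class resolution, and estimates historical effective population
    size from the decay of linkage disequilibrium via Sved's relationship.
    Includes a forward Wright-Fisher and pedigree simulator with full
    identity-by-descent truth tracking for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
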