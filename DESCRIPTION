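Package: SexLinkR
Title: Sex-Linked Marker Discovery and Sex Chromosome Assignment from
    Genotyping-by-Sequencing Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies sex-linked SNP and presence/absence (SilicoDArT-style)
    markers from reduced-representation genotyping matrices by call-ratio
    filtering, XY/ZW concordance scoring at a configurable threshold, and a
    homozygosity-based false-positive test; assigns the sex chromosome by
    aligning marker tag sequences to a reference genome (built-in seeded
    ungapped mapper or ingested BLAST tabular hits) and taking the modal
    chromosome among uniquely aligned markers. Includes a synthetic-data
    generator for XY/ZW scenarios with genotyping error, missingness,
    recombination, sex reversal, and between-population Y-haplotype
    introgression, so the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
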