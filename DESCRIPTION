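Package: sweepscan
Title: Haplotype-Based Selection-Signature Scans with iHS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects recent positive selection in phased diploid genomes with
    the integrated haplotype score (iHS). Provides site-level quality control
    for phased VCFs (missingness, minor allele frequency, an exact
    Hardy-Weinberg test and GATK-style INFO thresholds), extended haplotype
    homozygosity (EHH) curves and their trapezoidal integrals (iHH),
    frequency-bin standardization of ln(iHH_A/iHH_D), aggregation into 50 kb
    non-overlapping windows with top-percentile candidate-region calling,
    gene annotation of candidate regions by interval intersection, and QTL
    overlap with per-trait hypergeometric enrichment under
    Benjamini-Hochberg FDR control. A forward Wright-Fisher simulator with
    an optional hard selective sweep generates phased test data with known
    truth so the whole scan is reproducible without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
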