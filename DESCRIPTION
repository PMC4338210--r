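Package: haplodrift
Title: Haplotype-Based Selection Scans and Structured-Coalescent Simulation
    of Continental Allele-Frequency Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether a large allele-frequency difference
    between two continental population groups requires positive selection or
    is compatible with neutral drift under founder-effect demography.
    Implements extended haplotype homozygosity (EHH), relative EHH and the
    integrated haplotype score (iHS) from first principles on phased
    haplotype panels; a closed-form expected age for a neutral derived
    allele; chromosome-count-weighted regional pooling of per-population
    allele frequencies with frequency-differential summaries; a structured
    coalescent simulator of five demographic models of the peopling of the
    Americas (founder bottlenecks, exponential growth, island and
    stepping-stone substructure, circumarctic gene flow) scored by the
    proportion of neutral SNPs exceeding a frequency-differential threshold;
    and forward Wright-Fisher generators of synthetic sweep and neutral
    haplotype panels and multi-population frequency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
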