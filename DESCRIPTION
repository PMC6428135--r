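Package: ldnekit
Title: Linkage Disequilibrium, Runs of Homozygosity and LD-Based
    Effective Population Size from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising linkage disequilibrium (LD) in
    diploid SNP-array genotypes and for inferring historical effective
    population size (Ne) from LD decay. Reads and writes PLINK text
    PED/MAP genotypes; runs a marker/sample quality-control cascade
    (call-rate filters, Hardy-Weinberg exact test, minor-allele-frequency
    thresholds, random thinning); estimates pairwise D, D' and r2 from
    unphased genotypes by EM haplotype-frequency estimation with a
    haplotype-count sample-size correction; builds distance-binned LD
    decay tables, adjacent-pair per-chromosome summaries and non-syntenic
    background LD; detects runs of homozygosity with PLINK-style sliding
    window rules; and maps distance-binned adjusted r2 to an Ne
    trajectory through Sved's recombination mapping. A forward-in-time
    Wright-Fisher simulator with a piecewise-constant Ne history provides
    genotype datasets with known demographic truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
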