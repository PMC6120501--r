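Package: poolpig
Title: Replicated Pool-GWAS of Drosophila Pigmentation: CMH Association,
    Inversion Frequencies, Read-Pair Haplotypes and Factorial Effect
    Dissection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pooled extreme-phenotype genome-wide association
    (Pool-GWAS) as applied to thoracic trident pigmentation in Drosophila
    melanogaster. Reads and writes popoolation2-style synchronized allele
    counts, applies the coverage, minor-allele-count, read-placement,
    strand-bias and interval-mask site filters used in such studies, tests
    replicated light/dark allele-frequency contrasts with the
    Cochran-Mantel-Haenszel statistic (with Mantel-Haenszel odds ratios,
    Robins-Breslow-Greenland confidence intervals, autosomal count
    downsampling and empirical-null false-discovery control), estimates
    chromosomal inversion frequencies from marker SNPs and models them on
    the arcsine-square-root scale, counts multi-locus haplotypes and
    linkage disequilibrium from sequencing fragments spanning focal SNPs,
    simulates extreme-pool experiments from haplotype models under a given
    heritability, partitions transgenic phenotype variance with a
    full-factorial type-III ANOVA and eta-squared effect sizes, and
    generates synthetic datasets with known ground truth for all of the
    above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
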