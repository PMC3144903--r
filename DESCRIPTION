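Package: pkdscan
Title: Dominant-Segregation Variant Filtering, Parsimony Haplotyping and
    Grantham GV/GD Scoring for Canine Polycystic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for candidate-gene mutation hunts under an
    autosomal dominant model, built around the Bull Terrier polycystic
    kidney disease (BTPKD) locus in canine Pkd1. Provides a site-by-sample
    genotype table dialect with VCF-lite export, the
    heterozygous-in-all-affected / absent-in-all-unaffected segregation
    filter with a five-pattern exclusion taxonomy, exact minimum-haplotype
    parsimony phasing, cDNA-to-protein consequence annotation, Grantham
    distance and alignment-based GV/GD pathogenicity classification with
    the seven-grade (C0-C65) scheme, in-silico allelic-discrimination
    (TaqMan-style) genotyping from probe and primer sequences, and a
    synthetic cohort generator emulating a fully penetrant dominant allele
    on a shared founder haplotype with embryonic-lethal homozygotes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
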