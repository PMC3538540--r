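Package: popld
Title: Linkage Disequilibrium Decay and Haplotype Structure in
    Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes linkage disequilibrium (LD) in structured
    diploid populations genotyped on sparse regional SNP panels.
    Provides per-population SNP quality control (call rate,
    monomorphism, minor allele frequency), pairwise r-squared and
    D-prime from unphased genotypes via two-locus EM haplotype
    estimation, background (inter-chromosomal) LD, nonlinear fitting of
    the Hill-Weir drift-recombination expectation of r-squared with a
    50-percent-decay summary, fractions of GWAS-informative SNP pairs
    by distance class, solid-spine-of-LD haplotype blocks with
    EM-estimated haplotype frequencies, per-population heterozygosity,
    inbreeding coefficients and Tajima's D, Hudson-type pairwise Fst
    with neighbor-joining trees, and a forward Wright-Fisher simulator
    of breed bottleneck-and-expansion demographies for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
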