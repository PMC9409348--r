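Package: sexvarscan
Title: Sex-Associated Genomic Variant Discovery from Small Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of sex-associated genomic variation from a small
    (5 male / 5 female) whole-genome-sequenced cohort mapped to a reference
    genome. Implements genotype-pattern filtering on merged per-sample
    variant calls (quality-filtered males homozygous for the alternate
    allele, unfiltered females heterozygous or reference), a per-sample
    read-depth gate, 10 kb segment variant-density peak calling,
    nearest-gene assignment with bedtools-closest style tie-breaking,
    detection of genome regions covered exclusively in one sex, and
    pairwise dN/dS estimation by the Nei-Gojobori (1986) counting method
    with Jukes-Cantor correction. A fully specified synthetic-cohort
    generator with recorded planted truth makes every stage testable
    end-to-end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
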