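Package: mirsexdiff
Title: Small RNA-Seq Quantification and Sex-Difference Profiling for Four
    Core Genotypes Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mature and precursor miRNA expression from small
    RNA sequencing reads and profiles sex differences in expression across
    the Four Core Genotypes mouse design. Builds a collapsed and masked
    miRBase-style mapping reference with nested-pair accounting,
    demultiplexes, adapter-trims and length-filters raw reads, maps them
    ungapped with at most one mismatch, applies priority counting rules
    and nested-pair count subtraction, normalizes to counts per million,
    and computes group log2 expression-ratio distributions with exact
    binomial sign-bias tests, Wilcoxon rank-sum condition comparisons and
    library-level principal component analysis. Includes a synthetic-data
    generator that emulates the full 2 x 2 x 3 study design with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
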