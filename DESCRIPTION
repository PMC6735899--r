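Package: poolscreen
Title: Pooled-Colony Sequencing Screens for Drug-Resistance Mutation Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hydroxylamine-mutagenized plasmid pools and their short
    sequencing reads, aligns reads to an ORF amplicon under unique-placement and
    at-most-one-mismatch constraints, calls amino-acid substitutions from
    base-quality-filtered mismatches, ranks them by supporting reads with a top-N
    cutoff, and maps the resulting resistance landscapes onto protein domains,
    across phenotype screens and against validated-mutant phenotype tables. The
    workflow reproduces, at desk scale, the pooled-colony deep-sequencing strategy
    used to map drug-resistance mutation landscapes in topoisomerase II screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
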