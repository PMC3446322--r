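Package: gapmender
Title: Closing Intra-Scaffold Gaps in Draft Assemblies with Paired Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closes runs of N inside draft-assembly scaffolds using paired
    short reads. One mate of each pair is anchored to scaffold sequence and
    its partner is recruited to any gap the pair's insert-size window
    overlaps; recruited reads are split into k-mers and both gap edges are
    grown one overhang base at a time under coverage and majority-voting
    thresholds; a gap is accepted as closed only when the two extensions
    merge with sufficient overlap and the inserted sequence matches the
    scaffolder's gap-size estimate. Includes a wgsim-style paired-read
    simulator with truth tracking and an evaluator that classifies closure
    errors into SNPs and short/long indels, so the whole pipeline can be
    exercised on fully synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
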