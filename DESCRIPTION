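Package: scopclass
Title: Automated SCOP-Style Protein Domain Classification by Sequence
    Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Transfers SCOP-style domain boundaries and hierarchy
    placements from previously classified protein chains to new chains
    via filtered local-alignment hits. Reads and writes SCOP-compatible
    parseable files (dir.des, dir.hie, dir.cla) and ASTRAL-style domain
    and chain FASTA, groups and ranks alignment hits per target chain,
    assigns domain boundaries with terminus/gap extension and
    observed-residue clipping, gates predictions into a high-confidence
    set, places accepted domains in the class-to-species hierarchy, and
    benchmarks predictions against curated domains under a 10-residue
    same-superfamily correctness criterion. Includes a synthetic release
    generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
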