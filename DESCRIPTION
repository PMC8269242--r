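Package: primerscope
Title: Metagenome-Based Evaluation and Redesign of SSU rRNA PCR Primers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how well degenerate PCR primers match naturally
    occurring small-subunit rRNA sequences, using shotgun metagenomic reads
    aligned to group-specific SSU rRNA references. Extracts primer-binding
    region fragments from alignments, counts primer-template mismatches with
    full IUPAC degeneracy arithmetic, summarises perfect and near-match
    coverage per sample, taxonomic group and primer pair, enumerates
    naturally occurring primer-site variants, designs minimal explicit
    oligonucleotide mixtures as an alternative to fully degenerate primers,
    and quantifies concordance between amplicon-derived and
    metagenome-derived community composition. Includes a deterministic
    synthetic-data generator so the whole pipeline can be exercised and
    validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
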