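Package: rg4scope
Title: Transcriptome-Wide Detection and Profiling of RNA G-Quadruplexes
    from DMS-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects canonical RNA G-quadruplex (RG4) motifs in transcript
    sequences, computes per-nucleotide DMS-seq reactivities from reverse
    transcription stop counts, classifies each putative motif as observed
    (folded in-cell) or unfolded from its reactivity protection, and
    profiles the resulting sets along transcripts: region counts and
    per-kilobase densities, five-prime-end relative density profiles,
    metagene profiles around anchor sites such as miRNA target sites and
    putative PAS-strong poly(A) sites, quadruplex forming probability in
    positional bins, a Mann-Kendall trend test, and resampling-based
    expression comparisons. A fully specified synthetic transcriptome
    generator with planted motifs, Poisson stop counts, expression tables
    and anchor tracks makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
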