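Package: pddkit
Title: Probe-Directed Degradation Probe Design and Depletion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Design and screening of unmodified DNA depletion probes for
    probe-directed degradation (PDD) of unwanted sequences (typically rRNA)
    from single-stranded cDNA sequencing libraries. Provides nearest-neighbor
    DNA/DNA duplex thermodynamics and melting-temperature estimation, an
    exact-substring off-target scanner over a transcriptome, a model of
    duplex-specific nuclease (DSN) cleavage that predicts per-position
    depletion zones and validates probe spacing against library insert size,
    a seeded simulator of fragmented paired treated/untreated libraries, and
    read-level depletion and bias analyses (5' end-density ratio profiles,
    probe-anchored pileups, inter-probe statistics, depletion efficiency, GC
    content, and a reshuffling-based PCR-duplicate test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rsamtools,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
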