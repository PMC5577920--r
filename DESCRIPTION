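Package: psitrans
Title: Alternative Splicing Transitions Across a Developmental Time Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies percent-spliced-in (PSI) for cassette and mutually
    exclusive exon events from junction counts or band intensities, calls and
    time-classifies splicing and expression transitions across a postnatal
    developmental time course, classifies each alternative exon's reading-frame
    and protein-coding consequence against annotated gene models, and scores
    cross-species conservation of splicing transitions. Includes a fully
    deterministic synthetic-data generator (gene models with nucleotide
    sequences, planted splicing events, PSI trajectories, junction and
    expression counts, ortholog pairs) so every stage is testable against known
    ground truth, and a translation oracle that verifies coding-consequence
    calls by diffing translated isoforms.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
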