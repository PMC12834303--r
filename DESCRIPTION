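Package: gapfillr
Title: Deep-Learning Gap Filling for Draft Genome Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closes N-gaps in draft genome scaffolds with a character-level
    next-base neural network trained on the assembly itself. Gap-flanking
    sequence is one-hot encoded and fed to a convolutional + double
    bidirectional-LSTM network with a residual connection; candidate fills are
    decoded by a contraction-expansion beam search whose cost combines
    accumulated negative log-probability with entropy, remaining-length and
    GC-disparity heuristics; a prediction filter retains only candidates whose
    alignment rate against a homologous or truth region beats the unfilled
    baseline before patching the scaffold. Includes a seeded synthetic-genome
    simulator and assembly-quality metrics (fill rate, N's per 100 kb,
    mismatches per 100 kb, GC profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    GenomicRanges,
    jsonlite,
    optparse,
    rtracklayer,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
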