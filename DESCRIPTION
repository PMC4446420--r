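Package: inosine34
Title: Precursor-Resolved Detection of tRNA Wobble Inosine from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects A-to-I editing at the tRNA wobble position (residue 34)
    from small RNA-seq alignments, resolved by maturation stage. Reads are
    assigned to unique tRNA types across multi-copy gene families, classified
    as precursor (overlapping 5'-leader/3'-trailer sequence) or processed
    (contained in the mature gene span), piled up in a window around the
    anticodon, and summarised as A/G mismatch (inosine) proportions with
    Fisher exact tests and Benjamini-Hochberg adjustment between stages or
    between control and knockdown conditions. Includes a seeded small RNA-seq
    simulator with per-read modification truth, and in-silico counterparts of
    two biochemical inosine assays (Sanger readout of a deaminated pre-tRNA
    and Endonuclease V cleavage fragment prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    rlang,
    stats,
    tibble,
    tidyr,
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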