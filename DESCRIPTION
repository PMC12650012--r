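Package: g4strat
Title: Stratified Stability Analysis of G-Quadruplex Motifs from
    Sequencing Signal Proxies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects canonical and bulge-containing potential
    G-quadruplex sequences (PQS) in genomic DNA and decomposes each
    motif into the structural features known to govern quadruplex
    thermostability: G-tract length (tetrad layers), loop lengths and
    their permutation, bulge presence and size, loop base composition,
    and flanking sequence context.  Joins motifs to per-base stability
    proxies derived from polymerase-stalling sequencing assays
    (mismatch-percentage tracks, or Phred quality tracks transformed by
    ln(41.1 - x)) and produces feature-stratified reports with
    bootstrap-resampled group means and Wilcoxon rank-sum comparisons.
    Includes a fully parameterised synthetic genome and signal-track
    generator with an explicit thermostability model, so that every
    pipeline stage can be validated against known ground truth.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
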