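Package: nomephase
Title: Cluster-Based Phasing of Single-Molecule Chromatin Accessibility
    from Nano-NOMe-Seq
Version: 0.1.0
Authors@R:
    person("Nomephase", "Developers", email = "nomephase@example.org",
           role = c("aut", "cre"))
Description: Phases single-molecule GpC-accessibility profiles from
    nanopore NOMe-seq (nano-NOMe-seq) into long-range chromatin state
    clusters. Per-read methylation calls are binned into fixed-width bins,
    reads are clustered within overlapping windows by agglomerative
    average-linkage clustering under a masked Hamming distance that
    ignores missing data, window-level clusters are stitched across the
    locus by solving the optimal assignment problem with the Hungarian
    algorithm, and every molecule is finally reassigned to its
    best-matched stitched cluster series. Includes a leave-one-out
    long-read accuracy framework and a synthetic nano-NOMe-seq locus
    simulator with known latent accessibility states (nucleosome arrays,
    nucleosome-free regions, transcription-factor footprints) so every
    pipeline stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
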