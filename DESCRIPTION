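Package: karyoregion
Title: Sex-Determining Region Delineation and Catfish Karyotype Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delineates a sex-determining region on a chromosome-level
    assembly by integrating heterogeneous sex-linked evidence (QTLs,
    RAD tags, SSR/SCAR markers) through minimal quantile-covering
    windows, screens candidate sex-determining genes by
    direction-concordant differential expression across two contrasts
    with GO/KEGG annotation, and infers chromosome fusion/fission
    events and karyotype trajectories from pairwise synteny
    relationships. Includes seeded generators for every input so the
    whole pipeline is testable without external data, plus assembly
    summary statistics (N50/L50, anchoring coverage, gene density).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
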