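Package: contigwire
Title: Hybrid Genome Scaffolding from Contigs and Long Reads via Contig-Graph Wiring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders and orients pre-assembled contigs into scaffolds using
    high-fidelity long reads. Long-read ends are mapped to contigs with an
    alignment-free minimizer/minhash sketch mapper; shared reads define a
    contig graph whose edges carry link sets of read identifiers; a
    deterministic per-vertex wiring heuristic selects the best-supported pair
    of incident edges at each contig, and maximal edge-disjoint acyclic paths
    are enumerated from the wired graph; paths are partitioned into batches
    and turned into scaffold sequences by an anchor-based stitcher that fills
    gaps with spanning-read bases. A three-phase workflow (contig expansion,
    long-read island construction, bridge linking) produces final scaffolds
    with AGP output. Includes a synthetic-data generator with per-base ground
    truth and truth-based assembly metrics (N50/NG50, genome fraction,
    duplication ratio, misjoins).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
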