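Package: vgbarrel
Title: Deletion Variant Analysis for the Honeybee Vitellogenin Beta-Barrel
Version: 1.0.0
Authors@R:
    person("Vg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess a natural in-frame deletion in the honeybee
    Vitellogenin beta-barrel domain: indel discovery and population allele
    frequencies from haplotype coding sequences, per-residue conservation
    scoring with alignment-diversity summaries, comparative statistics for
    replicated molecular-dynamics trajectory ensembles (radius of gyration,
    RMSD, RMSF, sliding-window significance testing with false-discovery-rate
    control), essential-dynamics principal component analysis with
    residue-subset exclusion, and exhaustive in-silico deletion scanning with
    a pluggable scorer. Synthetic-data generators with known ground truth make
    every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
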