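Package: tetramap
Title: Linkage Mapping, Map Integration and Map-Based Scaffolding for
    Autotetraploid F1 Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genetic mapping in outcrossing autotetraploids from
    SNP-array dosage data. Simulates F1 crosses under polysomic inheritance
    with configurable quadrivalent and double-reduction rates, estimates
    pairwise recombination fractions and LOD scores by maximum likelihood
    under a bivalent polysomic model, builds linkage maps (duplicate-marker
    binning, LOD-ladder clustering into linkage groups, homologue assignment,
    weighted one-dimensional ordering with ill-fit pruning), integrates maps
    from two populations by LOD-squared weighted averaging of pairwise
    linkage data, anchors and orients contigs along the consensus map into
    AGP/FASTA pseudomolecules, characterises the recombination landscape via
    Marey maps, and provides BUSCO-driven contig purging plus standard
    assembly statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
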