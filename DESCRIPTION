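Package: paccer
Title: Quantifying Protein-RNA Interactions from Photoaffinity Competition
    Chemoproteomics
Version: 0.1.0
Authors@R:
    person("PACCE", "Maintainer", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for photo-activatable competition and
    chemoproteomic enrichment (PACCE) experiments, in which UV-crosslinked
    cellular RNA blocks a cysteine-reactive covalent probe at protein-RNA
    interfaces. Converts probe-modified peptide observations with SILAC
    channel intensities into protein-coordinate site ratios, classifies
    RNA-sensitive cysteines with an exact one-tailed Mann-Whitney U test
    against the 1:1 mixing control, performs binomial domain enrichment with
    Benjamini-Hochberg correction and hypergeometric set-overlap tests, and
    validates calls by minimum cysteine-to-RNA distances in protein-RNA
    structures. Includes a synthetic-data generator (proteomes, in-silico
    tryptic digests, SILAC PSM tables with planted competition effects, and
    toy coordinate files) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    rlang,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
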