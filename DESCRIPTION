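Package: fbmeta
Title: Meta-Omic Profiling of Fungal Fruiting-Body Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of shotgun metagenomes and metatranscriptomes
    sampled from fungal fruiting bodies. Converts per-gene read counts to TPM,
    assigns best-bit-score taxonomy from BLAST tabular hits, classifies sample
    decay status by bootstrapped Ward.D2 clustering of metagenomic profiles
    with a metatranscriptome rescue rule, parses KEGG module DEFINITION strings
    into boolean expression trees to score pathway completeness (including a
    nitrogenase subunit screen), and resolves CAZyme expression by substrate
    target and taxonomic origin. Ships a synthetic community generator with
    planted ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
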