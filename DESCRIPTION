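Package: sibmap
Title: SNP Array Design and Sex-Specific Linkage Mapping from Full-Sib Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing high-density SNP genotyping arrays from a
    fragmented draft genome and for building sex-specific genetic linkage maps
    from outbred full-sib families, modelled on aquaculture genomics practice
    (channel and blue catfish). Includes a synthetic-data generator (genome,
    variant pool, probe conversion scores, pedigrees with crossovers,
    genotyping error and missingness), a SNP filtering and greedy spacing
    selection cascade with array manifest reporting, sample and SNP conversion
    quality control, pedigree verification via identity-by-state distances,
    a two-point linkage mapping engine with Kosambi distances and linkage-group
    formation, sex-dimorphism G-tests, and scaffold anchoring with misassembly
    detection and AGP export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
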