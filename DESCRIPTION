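Package: ssrmine
Title: Reference-Free Mining and Validation of GBS-Derived SSR Markers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reference-free pipeline for mining simple sequence repeat
    (SSR, microsatellite) markers from genotyping-by-sequencing (GBS) reads:
    inline-barcode demultiplexing with restriction-site verification,
    exact-sequence read stacking and cross-accession locus cataloguing,
    MISA-style perfect SSR detection with canonical motif classes, flank-based
    locus clustering with codominant allele-table construction, PCR primer
    design under melting-temperature and GC constraints, and codominant-marker
    diversity statistics (allele numbers, MAF, expected and observed
    heterozygosity, PIC), Nei and allele-sharing distances, neighbor-joining
    trees, principal coordinates analysis and Mantel tests. Includes a
    ground-truthed simulator of ApeKI GBS libraries over genomes with planted
    SSR loci for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
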