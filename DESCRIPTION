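Package: partiq
Title: Quantification of Acyl-Adenosine Species from LC-HRMS Runs of
    RNase A-Digested tRNA (PARTI)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the computational workflow of the PARTI assay
    (3-Prime Adenosine-Retaining aminoacyl-tRNA Isolation): elemental
    composition arithmetic and exact monoisotopic masses for mono- and
    diacyl adenosine species released by RNase A cleavage of acylated
    tRNA, extracted ion chromatograms with ppm mass tolerance, peak
    detection and mass/isotope-envelope validation, internal-standard
    (leucine-enkephalin) normalization into A_norm values, percent
    acylation estimators, ionization-efficiency response factors,
    condition comparisons, design of biotinylated DNA capture
    oligonucleotides with nearest-neighbor melting temperatures, and a
    seeded synthetic LC-MS run generator with complete ground truth for
    end-to-end validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    pracma,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
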