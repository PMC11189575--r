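Package: uaaxl
Title: Identification of Unnatural-Amino-Acid Cross-Linked Peptides from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A search engine for cross-linked peptides formed by genetically
    encoded latent-bioreactive unnatural amino acids (Uaa) of the
    fluorosulfate-L-tyrosine (FSY/eFSY) class, which react with lysine,
    histidine and tyrosine via sulfur-fluoride exchange. Uaa-His and Uaa-Lys
    cross-links are MS-cleavable: the sulfamate bond fragments under HCD,
    releasing the two constituent chains and producing internal fragment ions
    that conventional cleavable and non-cleavable cross-link software does not
    model. The package provides the full chemistry and fragment-ion model
    (cleavable and non-cleavable modes), in-silico digestion, MGF/mzML
    spectrum input, candidate search with coarse scoring, semi-supervised
    linear rescoring with target-decoy q-values at the PSM level, a synthetic
    tandem-spectrum simulator with ground truth for benchmarking, and
    fragment-intensity ratio reports by cross-linked residue type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
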