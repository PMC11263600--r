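Package: glycosearch
Title: Layered Identification of N-Glycopeptides from Deconvoluted Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A glycan-first search engine for N-glycopeptide identification from
    charge-deconvoluted MS/MS peak lists. Enumerates peptide+Y ion ladders directly
    from glycan compositions with an approximate fragment-count normalizer, scores
    glycopeptide-spectrum matches with a mixed peptide/glycan model, layers on a
    learned fragmentation model (peak-relation reliability and multinomial relative
    intensity), site-specific glycome network smoothing, and a relative retention-time
    model that resolves quasi-isobaric composition/adduct ambiguities. Controls
    peptide, glycan, and joint false discovery rates by target-decoy competition with
    a semi-supervised linear-margin rescorer. Includes seeded synthetic-data
    generators for spectra and LC runs so every layer is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
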