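Package: proteomut
Title: Personalized Proteogenomic Identification and Quantification of
    Somatic Mutant Proteins
Version: 0.1.0
Authors@R:
    person("Urinary EV Proteogenomics Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: A desk-scale proteogenomic workflow for somatic mutant proteins
    in tumor tissue and extracellular-vesicle samples. Filters paired
    tumor/normal somatic variant calls, builds a patient-specific mutant
    protein sequence database (missense windows and frameshift neo-frame
    entries) merged with a reference proteome, identifies mutant peptides by
    in-silico tryptic digestion and target-decoy peptide-spectrum matching
    with q-value control and fragment-level mutation-site validation, and
    performs absolute quantification of mutant peptides from parallel
    reaction monitoring chromatograms against stable-isotope-labeled
    standards. A synthetic-data module generates every input the pipeline
    consumes so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
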