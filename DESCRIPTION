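Package: midaskit
Title: Design and Analysis Toolkit for Deterministic Deep Mutagenesis by
    PCR Assembly (MIDAS)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microbe-independent deep assembly and screening
    (MIDAS): design of enumerated saturation-mutagenesis primer arrays and
    overlap-extension PCR assembly plans (polytemplated/monotemplated,
    monofocal/polyfocal schemes), in-silico verification of assembled
    variant genes including plasmid re-amplification hazards, library
    economics calculators (error-prone PCR recovery frequencies,
    degenerate-library sizing, arrayed well counts), multiwell plate
    layout, and scoring of variant screens (vehicle/expression
    normalization, per-site mutational tolerance, substrate-specificity
    matrices with censoring, and four-parameter logistic dose-response
    fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
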