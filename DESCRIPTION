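Package: lipolyzer
Title: Quantification of In Vitro Lipolysis from pH-Stat and HPLC-ELSD Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying in vitro lipid digestion experiments.
    Computes free-fatty-acid release curves and initial lipolysis rates from
    pH-stat titration logs, fits power-law internal-standard calibrations for
    evaporative light-scattering detection (ELSD) and derives total and
    per-species triacylglycerol (TAG) lipolysis rates from peak-area tables,
    annotates reversed-phase chromatogram peaks by partition number, and
    summarises emulsion quality via the Sauter mean diameter and
    backscattering (Turbiscan-style) creaming and clarification rates.  A
    seeded synthetic-data generator produces every input type with known
    ground truth so each analysis stage can be verified end to end without
    laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
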