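Package: hecmscreen
Title: Screening Hepatotoxic Equivalent Combinatorial Markers from
    Chromatographic Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering hepatotoxic equivalent combinatorial
    markers (HECMs) in herbal-medicine LC-MS fingerprints. Annotates peaks
    against a compound library by theoretical negative-mode adduct m/z,
    builds common-peak fingerprint tables with cosine-similarity
    evaluation, screens toxicity-related peaks by partial least squares
    regression with variable-importance-for-the-projection (VIP) scores
    and by back-propagation neural-network mean impact values (MIV),
    clusters peaks with serum-enzyme endpoints, and tests hepatotoxic
    equivalence of a candidate marker combination against whole extracts
    with a two-one-sided-test 90 percent confidence interval against the
    (0.70, 1.43) limits. Includes a synthetic-data generator emulating the
    study design (21 fingerprints x 10 common peaks, two planted toxic
    peaks, per-animal ALT/AST endpoints) so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
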