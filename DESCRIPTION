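Package: peplife
Title: Prediction and Design of Peptide Half-Life in an Intestine-Like
    Protease Environment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Regression modelling of peptide half-life measured in crude
    intestinal protease preparations. Peptides are encoded as amino acid,
    dipeptide or tripeptide compositions or as positional binary profiles;
    models are fitted with epsilon-insensitive support vector regression,
    k-nearest-neighbour regression or a discretised decision table, with
    correlation-based feature-subset selection (CFS merit, best-first
    search) and five-fold cross-validated evaluation. Includes a
    physicochemical property panel, single-point mutant design, sliding
    window protein scanning, batch filtering, and a synthetic dataset
    generator with known generative structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
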