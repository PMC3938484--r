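Package: acidstress
Title: Chemiosmotic and Transcriptomic Analysis of Carboxylic Acid Stress
    in Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models and analysis utilities for studying octanoic acid (C8)
    toxicity in Escherichia coli. Provides a chemiosmotic proton-motive-force
    model with a shock/adaptation scenario solver contrasting strong inorganic
    acids with membrane-permeant carboxylic acids, intracellular pH inference
    from pH-dependent fluorescent-reporter calibration curves with
    detection-limit censoring, gene-wise permutation t-tests with pooled
    permutation nulls and false-discovery-rate filtering, network component
    analysis (NCA) for transcription-factor activity estimation over a fixed
    regulatory topology, membrane-lipid and growth physiology metrics, seeded
    synthetic-data generators emulating every pipeline input, and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
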