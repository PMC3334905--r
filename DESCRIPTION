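Package: cimplan
Title: Planning Calculus for Controlled In Meso Phase Crystallization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design calculus for vapor-diffusion-driven in meso (lipidic
    cubic phase) crystallization of membrane proteins on monoolein-precoated
    plates. Implements the equilibration mass balance that predicts the
    final hydration level of the monoolein/water system from the screen
    dilution factor, a monoolein mesophase classifier with an invertible
    hydration model for targeting specific phases, a Nernst partitioning
    model for protein uptake into the lipidic phase with apparent-K
    estimation from supernatant depletion assays, grid-screen and additive
    condition builders with 96-well plate layouts and robot-ready
    worklists, and a synthetic-assay generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
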