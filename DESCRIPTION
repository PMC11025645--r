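Package: langenc
Title: Voxelwise Encoding Models, Representational Generality, and
    Variance Partitioning for Language fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking why some stimulus representations predict
    brain responses to natural language better than others. Implements
    voxelwise ridge-regression encoding models with finite-impulse-response
    hemodynamic delays and Lanczos word-to-TR resampling; a linearly
    extractable next-word-prediction perplexity metric; a tournament-based
    representational-generality metric built from bottlenecked linear
    encoders and pairwise linear transfer decoders; and pairwise variance
    partitioning of held-out explained variance with signed R-squared. A
    synthetic-data module generates word streams from Markov chains with
    analytically known entropy rate, families of representations sharing a
    latent structure to varying degrees, and BOLD-like responses with
    repeats, so the full pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
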