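Package: pfspeller
Title: Particle-Filter Decoding for the P300 Speller with Language Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decodes P300 speller sessions by fusing stepwise linear
    discriminant analysis (SWLDA) stimulus scores with a character-level
    word-prefix language model through a sequential Monte Carlo (particle
    filter) posterior over typed strings, with dynamic stopping. Includes
    the 6x6 row/column stimulus protocol and its timing arithmetic, a
    synthetic session simulator with Gaussian target/non-target score
    models, and an evaluation suite computing selection rate, accuracy,
    correct characters per minute and the Wolpaw information transfer
    rate, plus threshold sweeps and three-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
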