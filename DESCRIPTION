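Package: fricshift
Title: Fricative Context Effects Under Simulated Cochlear-Implant Hearing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying phonetic context effects on the /s/-/sh/
    category boundary. Synthesizes a nine-step fricative spectral-peak
    continuum and vocalic contexts, degrades stimuli with a Greenwood-mapped
    noise-band vocoder, simulates trial-level four-alternative identification
    responses from a generative mixed-logistic categorization model, fits
    logistic and random-intercept logistic psychometric models with forward
    AIC selection, and converts fitted context effects into their equivalent
    shift of the fricative spectral peak in Hz.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    signal,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
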