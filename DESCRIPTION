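Package: rpeopt
Title: Batch Contextual Bayesian Optimization of iPSC-RPE Differentiation
    Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-loop search engine for cell-culture protocol optimization.
    Implements a Gaussian-process surrogate with an ARD-RBF kernel and fixed
    observation noise, expected-improvement acquisition, and a batch
    contextual local penalization (BCLP) policy that fills an 8-plate x
    6-well round of 48 culture conditions while honouring a per-well
    contextual trypsin-period parameter, together with the rule for shifting
    the trypsin context window between rounds. Also provides a pigmented-area
    image scorer (Gaussian blur, rolling-ball-style background subtraction,
    constant-threshold binarization, well-disc crop), a synthetic well-image
    generator with known ground truth, and a synthetic pigmentation-response
    oracle so multi-round campaigns can be simulated and benchmarked end to
    end without a robot or wet lab.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
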