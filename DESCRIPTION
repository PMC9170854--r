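Package: suvvar
Title: Statistical Technical Variation of SUV Metrics in PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the statistical technical variation of standardized
    uptake value (SUV) metrics in positron emission tomography (PET).
    A single acquisition is partitioned into disjoint shorter frames,
    SUVMax, SUVMean and SUVPeak are extracted per sphere and per frame,
    and the coefficient of variation measured within each subset is
    extrapolated to the full reconstruction length via the inverse
    square-root law of counting statistics. Includes a NEMA image-quality
    phantom simulator with Poisson count noise so the whole chain can be
    exercised and validated without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
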