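Package: secmp
Title: Effective Titer and Full/Empty Quantitation of AAV Products from
    SEC-UV and Mass Photometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies adeno-associated virus (AAV) preparations by combining
    dual-wavelength (280/260 nm) size-exclusion chromatography UV detection
    with mass-photometry particle counting. Integrates baseline-corrected
    chromatogram peaks, deconvolves capsid protein and encapsidated DNA
    contributions through a two-wavelength extinction-coefficient system,
    estimates the encapsidated genome size, classifies sample homogeneity
    from the single-particle mass distribution, and reports the effective
    (fully packaged) vector titer under three analysis scenarios. Includes a
    seeded forward simulator of both data types for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
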