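Package: phantomqc
Title: Intra- and Inter-Phantom Variability Analysis for Mammography QC Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the reproducibility of image-quality metrics
    measured on semicircular mammography quality-control test plates of the
    TORMAS type. Includes a synthetic phantom-image generator with controllable
    within-phantom (repositioning, quantum noise) and between-phantom
    (manufacturing) variability, automated extraction of 64 image-quality
    metrics (contrast-to-noise ratios of low- and high-contrast details,
    Droege-Morin bar-pattern MTF summaries, step-wedge contrasts, and
    structured-to-quantum noise ratios), defective-phantom screening, and an
    intra/inter-phantom variance-component decomposition with coefficients of
    variation and percent contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
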