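Package: fplcplot
Title: Parse, Annotate and Plot Preparative Liquid-Chromatography Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with UV chromatograms recorded on Akta (Unicorn)
    and other FPLC instruments. Reads the tab-separated and CSV curve exports
    produced by Unicorn software (including UTF-16 encoded files and
    comma-decimal locales) as well as a simple generic template for non-Akta
    instruments. Provides asymmetric-least-squares baseline fitting and
    subtraction, curve normalization, fraction-interval annotation,
    trapezoidal area-under-curve integration, zooming, and export of
    publication-quality annotated figures to PDF, EPS, TIFF and PNG. A
    synthetic chromatogram generator with known ground truth supports fully
    reproducible testing, and a small command-line interface supports batch
    plotting with persisted plot styles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    Matrix,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
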