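Package: hemodesign
Title: Hollow-Fiber Bioreactor Design Under Uncertainty for Red Blood
    Cell Biomanufacturing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A computational toolkit for designing and operating dual
    hollow-fiber bioreactors that produce red blood cells from
    hematopoietic progenitors. Couples a growth-factor-dependent
    compartment model of hematopoiesis with Krogh-cylinder mass
    transfer of nutrients, waste and growth factors, scores candidate
    bioreactor superstructures (fiber counts and types, geometry,
    flows, feeds) by cost per transfusion unit, and searches the
    design space globally. Supports worst-case robust optimization
    over box/level parameter uncertainty, one- and two-at-a-time
    elementary-effects sensitivity screening of the optimizer output,
    an explicit-geometry finite-difference cross-section solver for
    stress-testing the Krogh assumption, and a net-present-value
    market and labor analysis for the resulting cell therapy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
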