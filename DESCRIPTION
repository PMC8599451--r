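Package: myoquant
Title: Quantification Pipelines for Comparative Cardiac Injury Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implements, as tested and reusable functions, the
    quantification machinery of a comparative myocardial-infarction study
    (spiny mouse versus laboratory mouse after LAD ligation): QRS amplitude
    and duration from ECG traces, ejection fraction and fractional
    shortening from M-mode morphometry, hue-gated scar and heart-size
    morphometry over serial trichrome sections, Evans-blue infarct area,
    picrosirius birefringence hue profiles, collagen fiber waviness,
    structure-tensor anisotropy, box-counting fractal dimension and
    lacunarity, fluorescence cell-counting recipes (proliferation,
    capillaries, arteries, fibroblast coverage), and expression-level
    cardiomyocyte maturation analytics (variable-gene filtering,
    PC-loading gene selection, sample correlation networks, cumulative
    gene-set scores, ratiometric maturation signatures). Every input the
    pipeline consumes can be simulated with known ground truth, so all
    stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
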