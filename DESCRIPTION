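Package: aquage
Title: Reactor Number Balances and Confocal Biofilm Quantification for
    Drinking-Water Microbiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying microbial dynamics in bench-scale
    drinking-water reactors. Estimates the net growth/transfer rate (NGTR)
    of intact cells in a continuously stirred tank reactor with a wall
    biofilm, via instantaneous-steady-state and non-steady-state cell
    number balances on flow-cytometry intact cell counts. Quantifies
    three-channel confocal z-stacks of biofilm (nucleic-acid, protein and
    polysaccharide stains) into area coverage, maximum area, maximum
    biofilm height, biovolume and extracellular polymeric substance (EPS)
    metrics through median denoising, global Otsu thresholding,
    base-slice removal and channel merging. Includes derived
    water-quality metrics (intact fractions, ATP fractions, geometric
    summaries, Kendall tau-b), synthetic generators for reactor time
    series and z-stacks with exact ground truth, CSV/TIFF/YAML input and
    output, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
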