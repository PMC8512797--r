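Package: gridEMG
Title: Spatial Analysis of High-Density Surface EMG Activation Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for high-density surface electromyography (HDEMG) recorded
    from 2-D electrode grids: zero-phase band-pass preprocessing, force-triggered
    push-initiation windowing, RMS activation-map construction, normalization to
    maximum voluntary contraction (MVC), and the spatial map features intensity,
    differential intensity, mean RMS, modified entropy and coefficient of
    variation used to quantify the amplitude and spatial heterogeneity of trunk
    muscle activity. Includes a synthetic grid-EMG study generator with known
    ground-truth spatial structure for validating every pipeline stage, a study
    orchestration layer producing tidy per-trial feature tables and per-design
    summaries, and plain-text on-disk formats (channel-matrix CSV with JSON
    sidecars) plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, graphics, signal, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'errors.R'
    'AllGenerics.R'
    'AllClasses.R'
    'filter.R'
    'preprocess.R'
    'spatial-maps.R'
    'study-pipeline.R'
    'io.R'
    'cli.R'
    'layout-methods.R'
    'synthetic.R'
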