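Package: voltdemix
Title: Demixing and Analysis of Fluorescence Voltage and Calcium Imaging
    Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing high-speed fluorescence voltage-imaging
    and calcium-imaging traces from the mouse olfactory bulb and visual
    cortex. Converts raw fluorescence to (-)dF/F0 with rolling-median,
    sliding-percentile or pre-stimulus baselines, detects spikes by
    SD-threshold peak finding, and demixes dendritic regions of interest
    into glomeruli (correlation matrix + k-means) and putative single
    neurons (spike-synchronicity index + hierarchical clustering).
    Includes spike-triggered averaging with backpropagation latency maps,
    orientation-tuning curve fitting with OSI and tuning width, theta-phase
    spike statistics, and a synthetic-data generator with exact ground
    truth so that every stage can be verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
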