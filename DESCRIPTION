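Package: wctremor
Title: Phase-Locked Deep Brain Stimulation in a Stochastic Wilson-Cowan
    Tremor Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying phase-locked deep brain stimulation of
    essential tremor with a two-population stochastic Wilson-Cowan neural
    mass model.  Provides a fast Euler-Maruyama simulator with online
    zero-crossing phase tracking and burst stimulation reproducing the
    experimental block protocol; block-method extraction of phase and
    amplitude response curves (bPRC/bARC) from Hilbert phase and envelope;
    a statistics battery (Kruskal-Wallis, cosine-model F-tests, adaptive
    FDR control with a Storey estimate of the number of true nulls, and
    the PRC-ARC phase shift); analytic first-order response curves for the
    linearisation of a 2D stable focus; and derivative-free fitting of the
    model to tremor features by generalized pattern search.  Synthetic
    recording generators replace unavailable patient accelerometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
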