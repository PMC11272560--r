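Package: tdabreak
Title: Dynamic Topological Data Analysis and Fractal-Dimension Break Tests
    for Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting structural breaks in the evolving topology of
    multivariate time series. A signal is sliced into non-overlapping windows
    whose samples form point clouds; each cloud is summarized by the total
    persistence of its Vietoris-Rips filtration in homology dimensions 0, 1
    and 2, yielding time-varying total-persistence curves. Structural breaks
    in those curves are tested with a permutation test whose statistic is the
    Higuchi fractal dimension of the cumulative sum (CUSUM) of mean deviations:
    under the no-break null the CUSUM behaves like a random walk with fractal
    dimension 1.5, while a break drags it toward a smooth drift with dimension
    near 1. Includes a Rips persistence engine, Higuchi and box-counting
    fractal dimension estimators, fractional Brownian motion synthesis, and
    generators for the simulation designs (Gaussian/circle/sphere epochs and
    infinity/torus/spiral epochs) used to calibrate the test.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
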