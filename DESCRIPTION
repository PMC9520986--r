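Package: ringknots
Title: Random Knotting in Fractal Ring Polymers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo toolkit for studying how the random knotting
    probability of ring polymers depends on their fractal dimension.
    Samples Gaussian ring conformations of prescribed fractal dimension
    from a generalized Rouse ("beta") mode spectrum, classifies knotting
    of closed three-dimensional chains through the Alexander determinant
    (with KMT chain simplification) or, in two dimensions, through segment
    intersection, estimates unknot probabilities P0(N) and knotting
    lengths N0 by weighted exponential fits, and confronts the measured
    dependence of ln N0 on fractal dimension with an analytical
    double-exponential theory built on a generalized Flory argument.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
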