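Package: tgl
Title: Tilted Gradient Learning for Robust Variable Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-based estimation of a regression function's gradient
    field under the tilted empirical risk minimization criterion, for
    model-free variable selection that is robust to heavy-tailed noise and
    outlier contamination.  Implements the exponentially tilted pairwise
    squared loss on a reproducing kernel Hilbert space expansion, a
    gradient-descent solver with a provable fixed step size derived from
    strong-convexity and smoothness constants, coordinate-relevance
    rankings from per-coordinate RKHS norms or raw coefficient energy, and
    a synthetic-data generator for contamination robustness studies with
    Cauchy, scaled chi-square, and Gaussian noise over independent or
    AR(1)-correlated Gaussian designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
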