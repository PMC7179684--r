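Package: rebifactor
Title: Regularized Exploratory Bifactor Analysis for Small Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Exploratory bifactor analysis via the Schmid-Leiman
    orthogonalization with two factor-extraction engines suited to very
    small samples: iterative principal-factoring unweighted least squares
    (ULS) and regularized exploratory factor analysis (REFA), in which
    unique variances are a single shrinkage parameter times non-iterative
    tentative estimates and loadings follow in closed form. Includes
    oblique direct quartimin rotation by gradient projection, orthogonal
    Procrustes alignment, Tucker congruence and RMSE recovery metrics, and
    a Monte Carlo engine that generates multivariate-normal samples from
    independent-clusters population models over a factorial design grid,
    screens improper solutions, and summarises bifactor structure recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
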