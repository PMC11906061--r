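Package: sinegph
Title: Sine-G Baseline Hazards for Fully Parametric Proportional-Hazards
    Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trigonometric (Sine-G) families of survival distributions used
    as baseline hazards in fully parametric proportional-hazards regression
    for right-censored data.  Provides closed-form distribution functions for
    the sine-exponential, sine-Weibull, sine-Lomax, sine-exponentiated
    exponential and sine-Gompertz families; the right-censored
    proportional-hazards log-likelihood; inversion-method simulation of
    covariate-dependent lifetimes with calibrated censoring; maximum
    likelihood and Bayesian (Hamiltonian Monte Carlo or adaptive Metropolis)
    estimation with split R-hat, effective-sample-size and Monte Carlo
    standard-error diagnostics; WAIC and LOOIC model comparison from
    pointwise log-likelihood matrices; total-time-on-test hazard-shape
    diagnostics; and a command-line interface for simulate / fit / compare /
    ttt workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    coda,
    flexsurv,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
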