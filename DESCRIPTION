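Package: scalefx
Title: Scale-Effect Simulation of the Genetic Link Between Trait Mean and
    Environmental Variability
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte-Carlo machinery to quantify how much of the genetic
    correlation between a quantitative trait and its environmental (residual)
    variability is generated purely by the statistical scale effect, i.e. by a
    constant coefficient of variation linking the mean and the standard
    deviation. Simulates homoscedastic base populations, applies a
    per-individual scale-effect transformation, derives breeding values for
    the trait and for its log residual variance, and summarises scenario grids
    over heritability, coefficient of variation and scale-effect strength.
    Includes deterministic Gauss-Hermite quadrature oracles for verification,
    a quantile-bin diagnostic for real trait records, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
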