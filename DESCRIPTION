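Package: mssusmod
Title: Multilocus Threshold Model of Genetic Susceptibility to Multiple
    Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multilocus threshold ("n-of-x") model of genetic
    susceptibility to multiple sclerosis. Implements Hardy-Weinberg carrier
    and allele frequency algebra, relative-class transmission probabilities
    (siblings, parents and children, second and third degree relatives, and
    offspring of conjugal couples), a constraint solver for the number of
    susceptibility loci compatible with the observed HLA-negative case
    fraction, predictors of disease prevalence and familial recurrence risk,
    a Closeness-of-Fit grid search over model configurations, and a forward
    Mendelian pedigree simulator that acts as a brute-force oracle and
    synthetic-data generator. All inputs are scalar epidemiological
    constants; no external data are required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
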