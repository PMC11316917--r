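Package: sizestab
Title: Body-Size-Dependent Resistance, Niche Breadth and Assembly of Soil
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline relating microbial body size to community
    stability in paired control/disturbance incubation designs. Computes
    the Orwin-Wardle resistance index, tolerance widths and community
    nonsynchronization, Shannon diversity and Levins niche breadth,
    permutation-null classification of habitat generalists and
    specialists, Sloan neutral community model fits and a normalized
    stochasticity ratio, and links organism groups to ecosystem
    multifunctionality through Spearman correlations and body-size
    regressions. Includes a synthetic community generator with planted,
    recoverable structure and a neutral-assembly simulator so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat
Config/testthat/edition: 3
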