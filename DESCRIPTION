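Package: tetracross
Title: Tetrad Analysis of Meiotic Crossovers and Interference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification of meiotic recombination from fluorescent pollen
    tetrads. Classifies three-marker tetrads into parental ditype, tetratype
    and non-parental ditype categories, estimates Perkins map distances with
    delta-method sampling variances, compares genotypes with Z-tests,
    estimates the interference ratio on adjacent intervals and tests for
    absence of interference, and summarises metaphase-I bivalent and
    recombination-focus counts. Includes a two-pathway crossover simulator
    (interfering class I crossovers from a stationary gamma-renewal process,
    non-interfering class II crossovers from a Poisson process) that
    generates synthetic tetrad populations and meiocytes with controllable
    interference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
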