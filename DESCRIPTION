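Package: ncdbench
Title: Benchmarking National Trends in Non-Communicable Disease Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the unconditional probability of dying from a set of
    non-communicable disease (NCD) causes between two exact ages, in the
    absence of competing causes of death, from abridged-lifetable death
    rates; classifies decadal trajectories of change in that probability;
    decomposes changes, decadal differences in change, and gaps to a
    regional benchmark country into cause-of-death and age-group
    contributions with the Horiuchi continuous-change method; and
    propagates Poisson sampling uncertainty into percentile intervals.
    Includes a synthetic mortality-surface generator with Gompertz age
    gradients, age-varying cause composition, and period-specific
    log-linear trends, so the full pipeline runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
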