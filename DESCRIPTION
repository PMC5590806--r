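Package: bmpgrad
Title: Model-Based Screening of BMP Dorsoventral Gradient Formation Mechanisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to study how the BMP signaling gradient that patterns the
    zebrafish dorsoventral axis is formed. Implements a one-dimensional
    reaction-diffusion model of BMP, Chordin, Noggin, their complexes and
    Tolloid cleavage on the embryo half-circumference; a random-parameter
    computational screen with deterministic checkpoint/restart; fitting of
    screened solutions against ventral-to-dorsal P-Smad5 intensity profiles
    with mechanism classification (source-sink, counter-gradient,
    transcriptional, shuttling); construction of marginal intensity profiles
    from nuclei point clouds; estimation of effective diffusivities from
    fluorescence recovery after photobleaching (FRAP); and synthetic-data
    generators for all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
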