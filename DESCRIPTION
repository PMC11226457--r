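Package: ajmech
Title: Quantitative Mechanics of Adherens Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis stack for quantitative adherens-junction mechanobiology:
    scanning-angle interference microscopy (SAIM) axial nanometry with a
    thin-film standing-wave forward model and per-pixel height fitting;
    worm-like-chain prediction and classification of single-molecule
    magnetic-tweezer rupture steps; FRAP double normalization and
    single-exponential recovery fitting; laser-ablation junction recoil
    rates; and angular statistics of collective migration velocity fields.
    Each stage is paired with a seeded synthetic-data generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    jsonlite,
    tiff,
    yaml,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
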