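Package: syconpump
Title: Hydrodynamics of Gasket-Less Sponge Pumping Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models pumping and filtration in the flagellated chamber of
    syconoid (calcareous) sponges, which lack the physical gasket that seals
    the collar filter in high-pressure leucon sponges. Provides a quasi-steady
    low-Reynolds-number flow solver for a periodic unit cell of the chamber
    (one ostium surrounded by 24 choanocytes) with beating vaned flagella
    imposed as moving no-slip sheets and microvillar collars homogenised as
    Brinkman porous shells; the linear pump/system characteristic framework
    (maximum pressure, maximum flow, canal resistance, operating point);
    passive-tracer particle tracking for collar encounter efficiency; and the
    experimental pipeline for dye-front excurrent flux and paired
    inhaled/exhaled (In-Ex) retention-efficiency statistics, together with a
    synthetic-data generator for testing that pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
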