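Package: hrulci
Title: Source-Sink Landscape Analysis of Non-Point Source Pollution with
    Hydrological Response Units
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the spatial arrangement of source and sink land-use
    types in a watershed promotes or inhibits the transmission of non-point
    source pollutants (total nitrogen, total phosphorus, chemical oxygen
    demand) to the stream network.  Provides a lightweight raster data model
    with ESRI ASCII grid input/output, the eight classical landscape pattern
    metrics (NP, PD, LPI, LSI, AWMSI, ENN_MN, IJI, AI), D8 flow routing with
    depression filling, stream extraction and sub-basin delineation,
    hydrological response unit (HRU) construction by land-use/soil overlay,
    export-coefficient style geographic correction factors, and the
    HRU-based location-weighted landscape contrast index (HRULCI) together
    with seeded synthetic basin generators so the whole pipeline can be run
    and tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
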