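Package: cobraclim
Title: Climate-Envelope Range Change and Human-Pressure Accounting for Asian Cobras
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits BIOCLIM-style percentile climate envelopes to species
    occurrence records, projects them onto present and future (multi-GCM,
    multi-RCP) bioclim grids, builds ensemble-consensus suitability maps,
    derives lost/gained/stable change zones, converts zones to areas and to
    time-to-Red-List-Vulnerable estimates under the IUCN criterion B1 extent
    threshold, and overlays human-population pressure per zone. Ships a
    deterministic synthetic-data generator (climate stacks with GCM
    perturbations and future shifts, occurrences drawn from a known envelope,
    land masks, clustered population rasters) so the whole pipeline is
    testable offline with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, geosphere
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
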