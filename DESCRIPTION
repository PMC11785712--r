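Package: vinoclim
Title: Climate Variability and Wine Composition Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links regional climate variability to wine composition,
    production and phenology in Mediterranean-continental vineyard regions.
    Computes viticultural bioclimatic indices (Growing Degree Days, Huglin
    heliothermal index, Cool Night Index, Dryness Index) from daily station
    records; summarises annual vintage tables by mean-centered principal
    component analysis; provides from-scratch nonparametric statistics
    (Mann-Kendall, Theil-Sen, partial correlation with a control variable,
    Kruskal-Wallis, Conover-Iman, critical correlation thresholds);
    implements tercile-composite monthly anomaly analysis with bootstrap
    significance envelopes; and handles gridded leaf-area-index and
    sea-surface-temperature fields (vineyard-pixel selection, regional
    series, seasonal means, correlation maps). A bundled stochastic
    generator produces daily weather, vintage tables, LAI grids,
    teleconnection indices and SST fields with known ground-truth couplings
    so every stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ncdf4
Config/testthat/edition: 3
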