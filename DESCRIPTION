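Package: fjordwave
Title: Hydrographic Anomaly Detection and Abiotic-Biotic Coupling for
    Coastal Observatory Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects marine heat waves, cold spells and salinity anomalies
    in daily observatory time series against day-of-year percentile
    climatologies, standardizes weekly stereoscopic survey counts to catch
    per unit effort (CPUE), aggregates anomaly day-degrees into polar
    cohort years (01 August through 31 July), and couples abiotic and
    biotic anomalies through Mann-Kendall trend tests and rank-on-rank
    least-squares regression. Includes a synthetic observatory-data
    generator with injected events and configurable abiotic-biotic
    coupling for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
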