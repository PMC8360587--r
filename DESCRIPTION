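Package: ssii
Title: Species Status Information and Sampling Effectiveness Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes indicators of spatiotemporal biodiversity data coverage
    and sampling effectiveness from species occurrence records, expected-range
    layers, and national boundaries indexed on an equal-area grid. Implements
    the Species Status Information Index (SSII, the proportion of a species'
    expected range cells with occurrence records in a year), its national and
    stewardship-weighted aggregations, and the Species Sampling Effectiveness
    Index (SSEI, normalized Shannon entropy of the per-cell record
    distribution). Includes annual time-series aggregation, decadal trend
    detection with significance testing, a four-quadrant national typology,
    a synthetic-world generator for validation, and delimited-text
    interchange readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
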