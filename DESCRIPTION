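Package: gulfcross
Title: Wind Selectivity and Trans-Gulf Trajectory Simulation for Nocturnal Migrants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying wind-supported nocturnal bird migration across
    a large water barrier such as the Gulf of Mexico. Provides a synthetic
    generator for reanalysis-like gridded wind fields and bird-night records,
    inverse-distance-weighted wind interpolation, the tailwind ("wind profit")
    statistic and nightly wind summaries, a forward trajectory model that
    advances simulated migrants along loxodromes under hourly-updated winds,
    Monte-Carlo randomization tests of arrival and departure selectivity,
    forecasting-consistency metrics, and flight-range arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    pracma
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'gulfcross-package.R'
    'classes.R'
    'sampling.R'
    'twilight.R'
    'windfield.R'
    'mask.R'
    'io.R'
    'trajectory.R'
    'birdnights.R'
    'selectivity.R'
    'forecasting.R'
    'flightrange.R'
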