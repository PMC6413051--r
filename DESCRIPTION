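Package: skiturn
Title: Turn-Switch Detection from Boot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects alpine-ski turn switches (edge changes) from angular
    velocity recorded by inertial measurement units mounted on the upper cuff
    of each ski boot. Implements the gyroscope z-axis and gyroscope resultant
    detection algorithms (strong low-pass windowing followed by a windowed
    extremum search on a zero-lag Butterworth filtered signal), a
    Bland-Altman limits-of-agreement framework with reference-adjusted
    precision for evaluating event-timing methods against multi-rater video
    annotations, a three-step variant selection pipeline over the full
    sensor x axis x source x cutoff grid, and a ski-ergometer session
    simulator with exact ground-truth switch times for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
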