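Package: rhythmgrid
Title: Behavioral-Rhythm Feature Extraction from Smartphone Passive Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests per-participant smartphone passive-sensing logs (GPS fixes,
    mother-infant Bluetooth proximity scans, activity-recognition labels, and
    clip-level audio sound-class predictions) in a dated per-day file convention,
    quantizes each sensor stream onto a 96-bin 15-minute daily grid with explicit
    missing data, codes each hour of the day as together/apart, active/inactive,
    and speech/no-speech, derives GPS mobility summaries (radius of movement,
    farthest distance from home, fraction of time outside the home, heat-map
    count grids), evaluates configurable behavioral-activation award rules, and
    assembles weekly counselor-facing reports. Includes a seeded daily-schedule
    simulator that emits sensor files in the same convention together with
    ground-truth hour labels, so the whole pipeline can be tested end to end
    without device data.
License: MIT
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
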