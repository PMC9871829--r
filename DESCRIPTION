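Package: skipack
Title: Pack Dynamics and Pacing Analysis for Mass-Start Cross-Country Ski
    Races from GNSS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing mass-start cross-country skiing races from
    10 Hz GNSS position tracks. Builds a 1 m-resolution reference course by
    averaging all skiers and laps, segments the elevation profile into
    uphill, flat and downhill terrain, map-matches individual tracks onto
    the course to obtain monotone distance-time traces and lap/segment
    speeds, detects packs of skiers with the 3 s consecutive-gap rule and
    tracks their splits and merges, quantifies the accordion effect
    (backward-propagating decelerate-accelerate waves), decomposes time
    loss relative to the leading group by terrain, and reconstructs full
    speed profiles for skiers with only official split times. A seeded
    agent-based race simulator with ground truth supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
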