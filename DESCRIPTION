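Package: geoaccess
Title: Geospatial Accessibility and Bypassing of Health Facilities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Point-pattern and accessibility analysis of health-facility
    networks on planar (projected) coordinates. Implements the Clark-Evans
    average nearest-neighbour test classifying a facility point set as
    clustered, random or dispersed; Getis-Ord Gi* hotspot mapping on a
    fishnet grid with Benjamini-Hochberg false-discovery-rate correction and
    signed confidence bins; Euclidean nearest-facility assignment with
    hub-line construction, facility-bypassing classification and distance
    summaries; insurance-coverage statistics by administrative stratum and
    Leslie Kish sample-size calculation. Ships a synthetic-data generator
    (complete spatial randomness, Thomas cluster and lattice facility
    patterns; distance-decay facility choice; landmark-proxy positional
    jitter) so the whole pipeline is testable without field data, plus
    CSV/GeoJSON readers and writers and a reproducible run orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
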