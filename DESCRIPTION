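Package: jumpsim
Title: Forward-Dynamics Simulation of Maximum-Effort Vertical Jumping in Bipeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Planar musculoskeletal models of bipedal vertical jumping with
    Hill-type aggregated muscle actuators, soft hinge joint limits, unilateral
    spring-damper ground contacts and midshaft bone-stress constraints.
    Provides three muscle reconstruction schemes (measured parameter tables,
    schematic mass partitioning and regression prediction from bone areas),
    range-of-motion fibre-length estimation, a genetic-algorithm search over
    activation patterns that maximises centre-of-mass height under a time
    limit, and the standard force-plate jump performance metrics
    (countermovement/squat phase detection, take-off velocity, relative net
    vertical impulse, ballistic apex prediction). Ships reference human and
    guineafowl model fixtures and a synthetic trace generator with known
    ground-truth metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
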