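Package: foragescape
Title: Central-Place Foraging Analysis from GPS Tracks: First-Passage Time,
    Utilization Distributions, Presence-Only Habitat Models and Isotopic Niches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the spatial and trophic ecology of central-place
    foraging seabirds tracked by GPS. Segments tracks into colony-anchored
    foraging trips and computes trip metrics; detects area-restricted search
    (ARS) scales and zones by two-stage first-passage-time analysis; estimates
    kernel utilization distributions with least-squares cross-validated
    bandwidths, probability contours, volume-intersection overlap and overlap
    with conservation-layer polygons; fits and evaluates presence-only
    maximum-entropy habitat suitability models with replicate AUC, jackknife
    and permutation variable contributions; and summarizes bivariate stable
    isotope niches by standard ellipse areas (SEA, SEAc), Bayesian posterior
    areas (SEA_B), ellipse overlap and Layman metrics. Includes seeded
    correlated-random-walk and environmental-field simulators with attached
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
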