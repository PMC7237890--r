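Package: perivax
Title: Quantification of Directional T Cell Migration Along Perivascular Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying directional lymphocyte migration along
    perivascular stromal tracks in intravital two-photon time-lapse imaging of
    the spleen. Includes an agent-based generator of synthetic calibrated
    time-lapse stacks and ground-truth track tables under a compartmental
    migration model with perturbation presets (CCR7 knockout, pertussis toxin,
    integrin blockade, LPS inflammation); centroid detection, greedy
    nearest-neighbour track linking and mask shape metrics (circularity);
    per-track motility metrics (mean velocity, straightness, motility
    coefficient); a binary toward/away-T-zone track classifier with
    branch-point exclusion; a superpixel dense-optical-flow collective-motion
    statistic with vessel-axis projection; and fixed-ROI density
    quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
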