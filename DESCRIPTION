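Package: pbtrack
Title: Tracking and Motion Statistics for P-Body Granules in Yeast Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects fluorescent P-body granules in time-lapse microscopy of
    budding yeast by Difference-of-Gaussians band-pass filtering and Gaussian
    point-spread fitting, segments cells from bright-field focus stacks by
    marker-based watershed, links detections into trajectories, and computes
    motion statistics tailored to mother-to-daughter granule transport:
    k-means positional clustering with a reversibility rate and cluster
    betweenness, step sizes and velocities, mean-squared-displacement and
    windowed diffusion coefficients, and changepoint detection of confined
    ("hovering") motion near the bud site. A synthetic-data module generates
    ground-truthed trajectories, fluorescence frames and bright-field stacks
    so every stage of the pipeline can be validated without raw image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
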