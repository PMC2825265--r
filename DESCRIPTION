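Package: ethoproto
Title: Prototypical Movement Discovery from Behavioural Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic, objective discovery of prototypical behavioural
    components from continuous movement recordings. Extracts body-frame
    translational and rotational velocity features from 6-DOF trajectories
    (zero-phase Butterworth smoothing, z-normalisation), constrains the
    number of clusters with a Ward-criterion agglomerative pre-scan,
    estimates prototypes with restarted Lloyd k-means, and selects the
    number of prototypes with a centroid-based validation framework:
    systematic leave-out resampling, Hungarian-matched centroid instability,
    mean sets of centroids, and a per-cluster separation/compactness quality
    index. Label sequences are segmented into maximal runs of constant
    prototype, yielding durations of prototypical movements such as saccades
    and intersaccades in insect flight. Includes synthetic generators for a
    Gaussian-mixture benchmark and fly-like saccadic flight with ground
    truth, plus modified star-plot visualisation of prototypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
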