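Package: dynifs
Title: Dynamic Bone-to-Bone Distance from Motion Capture and Subject-Specific Bone Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures dynamic bone-to-bone distances, in particular the
    ischiofemoral space (IFS), by registering skin-marker motion-capture
    trajectories to subject-specific bone surface models. Provides
    closed-form SVD (Kabsch) rigid registration of corresponded landmark
    sets, per-frame bone pose estimation from marker clusters, gait-event
    detection from ground-reaction forces, time-normalization of distance
    curves to the gait cycle, minimum mesh-to-mesh distance between
    cortical regions of interest, a sphere-phantom validation protocol
    with RMSE, coefficient-of-multiple-correlation and linear-fit metrics,
    and one-dimensional SPM/SnPM inference (random-field-theory and
    max-statistic permutation thresholds) for comparing gait-normalized
    waveforms between groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
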