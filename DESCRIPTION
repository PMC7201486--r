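Package: birddogcv
Title: Computer-Vision Indices of Postural Control from Pose Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies postural control during the bird-dog (one arm and one
    leg balance) task from 2D pose-estimation keypoints in the OpenPose
    BODY_25 JSON dialect. Computes three per-trial indices: duration time
    (DT, capped at the task maximum), static postural balance (SPB, the
    z-scored log-inverse of the body-length-normalized per-frame displacement
    of the extended limbs' keypoints) and antigravity posture (AG, the
    z-score of the negated mean absolute limb-floor angle). Provides the
    cohort-level validation analyses: Spearman rank correlations with
    therapist ratings, standardized-coefficient regression comparing a
    DT-only model with a model adding the vision-based indices, test-time
    truncation curves, and ICC(2,1) interrater reliability. Includes a
    deterministic synthetic-cohort simulator with known ground truth and a
    command-line interface for end-to-end simulate/score/analyze runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
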