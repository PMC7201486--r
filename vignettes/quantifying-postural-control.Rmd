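---
title: "Quantifying bird-dog postural control from pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bird-dog postural control from pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birddogcv)
```

## The task and the measurement problem

The one-arm-and-one-leg balance ("bird-dog") task asks a child to hold a
four-point crawling posture with one arm and the contralateral leg lifted
and extended horizontally, for up to 60 s per side. Clinically the task has
been scored only by its duration time (DT) — the seconds until a lifted
limb touches the floor, capped at 60 s. That single number misses the
qualitative aspects therapists actually watch: how steady the posture is,
and how well the limbs are held up against gravity.

`birddogcv` quantifies those aspects from markerless pose estimation. The
input is the BODY_25 keypoint stream a pose estimator (e.g. OpenPose) emits
for a sagittal-plane video: per frame, 25 named landmarks with image
coordinates and a detection confidence in [0, 1]. Because such detectors
are trained on upright people, quadrupedal videos are rotated 90° head-up
before detection and the keypoints rotated back afterwards;
`rotate_frame()` implements both directions of that convention, and the
package's canonical orientation is the original (participant-horizontal)
video frame with the image origin top-left and y growing downward.

## The three indices

**DT (duration time, s).** `DT = (fall frame − start frame) / fps`, capped
at the task maximum (`task_cap_s`, 60 s); a posture held to the end of the
recording scores the capped remaining length. Because the original protocol
determines these events from the video without prescribing an algorithm,
`duration_time()` offers two modes: `annotated` (trusted start/fall frame
ordinals supplied with the trial, the default) and `heuristic` (posture
onset = extended wrist and ankle clear of the floor line by
`lift_margin_bl` = 0.1 body lengths with both limb angles under
`extension_angle_max` = 30°; fall = either keypoint returning within
`floor_margin_bl` = 0.02 body lengths of the floor line, which is taken to
be the lowest point reached by the supporting wrist/ankle unless
overridden).

**SPB (static postural balance, z-score).** For each of the extended
limbs' wrist, elbow, ankle and knee keypoints, the mean per-frame moving
distance is

$$D = \frac{1}{n-1} \sum_{i=1}^{n-1} \frac{\lVert p_i - p_{i-1} \rVert}{bl},$$

where the body length $bl$ is the mean neck-to-mid-hip keypoint distance
over the trial — normalizing by it removes body-size and camera-distance
effects, so $D$ is in body lengths per frame. The four distances are
averaged, $D' = (D_w + D_e + D_a + D_k)/4$, and the cohort-standardized
index is

$$\mathrm{SPB}_j = \frac{\log(1/D'_j) - \mu}{\sigma},$$

with $\mu, \sigma$ the mean and sample standard deviation of
$\log(1/D')$ across all trials. High SPB = steadier posture.

**AG (antigravity posture, z-score).** Per frame, the arm vector runs from
the neck to the midpoint of the extended arm's wrist and elbow, the leg
vector from the mid-hip to the midpoint of the extended leg's ankle and
knee. With $\varphi$ and $\theta$ their absolute angles to the floor
(assumed parallel to the image's horizontal axis),

$$a = -\frac{1}{n} \sum_{i} \left( |\varphi_i| + |\theta_i| \right),$$

so $a \le 0$ with 0 for perfectly horizontal limbs, and both drooping and
over-raising are penalized. AG is the cohort z-score of $a$; high AG =
limbs held close to horizontal.

Preprocessing before any index: keypoints with confidence strictly below
`confidence_threshold` (0.5) are removed and refilled by linear
interpolation against frame index, per coordinate. Frames in which the
detector found nobody are treated as fully undetected (confidence 0), so
they merge into the same gap-filling path.

## Validation analyses

Against a table of therapist ratings (several raters on a 1–7 scale,
averaged into TQCE, with `icc_2_1()` for their agreement), the package
reproduces the validation design:

1. `spearman_cor()` — rank correlations of SPB, AG and DT with TQCE, with
   the t-approximation p-value (exact permutation available for n ≤ 10).
2. `fit_tqce()` — ordinary least squares on z-scored response and
   predictors, so coefficients are standardized betas (for one predictor,
   the Pearson r); it reports SEs, adjusted $R^2$ and keeps unstandardized
   coefficients alongside. `predicted_correlation()` gives the Spearman
   correlation of a model's fitted values with TQCE, the headline
   comparison between the DT-only and the SPB+AG+DT model.
3. `truncate_and_reanalyze()` — simulates shorter test times: for each
   time $T$, frames after $\min(\text{fall}, T)$ are discarded, DT is
   capped at $T$, $D'$ and $a$ are recomputed on the truncated frames,
   SPB/AG are re-standardized within the truncated cohort, both models are
   refitted and correlated with the *full-length* ratings (the raters are
   not re-collected). At $T$ = 60 s this reproduces the untruncated
   pipeline bit-for-bit, because full-length scoring itself uses the
   window from the start frame through the fall frame.

## Tunable parameters

| key | default | unit | role |
|---|---|---|---|
| `confidence_threshold` | 0.5 | — | strict `<` masks a detection |
| `d_prime_floor` | 1e-6 | bl/frame | floors $D'$ before $\log(1/D')$ |
| `task_cap_s` | 60 | s | task maximum; DT cap and analysis window |
| `dt_mode` | annotated | — | DT from metadata or from keypoints |
| `lift_margin_bl` | 0.1 | bl | heuristic posture-onset clearance |
| `floor_margin_bl` | 0.02 | bl | heuristic floor-contact margin |
| `extension_angle_max` | 30 | deg | heuristic extension criterion |

## Numerical and design choices

* **Natural log** in SPB. The log base only rescales $\log(1/D')$
  linearly, and a z-score is invariant under linear rescaling, so any base
  gives identical SPB values; the natural log is the canonical choice.
* **Sample standard deviation (n − 1)** for every z-score, and the
  mean-0/sd-1 identity is checked with the same estimator.
* **Edge gaps** cannot be linearly interpolated, so leading/trailing
  masked frames take the nearest valid value (constant extension) rather
  than an extrapolated one.
* **Hip = mid-hip** (BODY_25 index 8), the sagittal-plane trunk landmark,
  both for the body length and the leg vector.
* **Angles in degrees**; standardization makes AG unit-free anyway.
* **Multi-person frames** keep the person with the highest summed
  confidence — a deterministic rule for plumbing that records one child.
* **Standardization cohort** = all trials (participant × side), matching a
  68-trial design; `truncate_and_reanalyze(restandardize = FALSE)` switches
  to reusing the full-length μ, σ if a fixed scale is preferred.
* **Degenerate inputs** raise classed conditions rather than silently
  propagating: an all-masked keypoint aborts its trial
  (`all_masked_error`), coincident neck/hip or limb endpoints are
  `degenerate_body_error` / `degenerate_limb_error`, a constant cohort is
  `constant_cohort_error`, and near-collinear predictors (condition number
  above 1e8) are `collinearity_error`. The command-line runner logs
  per-trial failures and continues.

## What the synthetic cohort emulates

`generate_trial()` builds a sagittal skeleton (neck-to-hip length 200 px in
a 1280×720 frame, 30 fps by default) with the supporting wrist, knee and
ankle on the floor line and the extended limbs at a mean droop angle.
Controllable features, chosen to mirror the recorded study design they
stand in for:

* **Sway**: mean-reverting (AR(1), ρ = 0.95) Gaussian perturbation of the
  extended-limb keypoints with per-frame step sd `sway_sigma` body
  lengths, so $D'$ grows monotonically with `sway_sigma` without the limbs
  drifting off-body.
* **Droop**: both extended limbs at `droop_deg` below horizontal, giving
  $a \approx -2\,\texttt{droop\_deg}$.
* **Fall**: at `fall_time_s` the extended wrist and ankle drop to the
  floor line; the frame ordinal is recorded as the annotated fall.
* **Detection noise**: confidences are drawn in [0.6, 0.95] with a
  `dropout_rate` fraction replaced below 0.5, exercising the masking and
  interpolation path. In the noiseless limit (zero sway, droop and
  dropout) the pipeline returns $D'$ at the floor value, $a = 0$ and DT at
  the cap, exactly.

`generate_cohort()` draws per-trial parameters (sway and droop uniform,
fall times lognormal with meanlog log 24 and sdlog 1.2, so roughly a
quarter of trials last the full 60 s and roughly half reach 20 s, matching
the reported design), derives per-trial child seeds from the master seed by
a fixed counter scheme, and simulates raters: a latent quality
$q = 0.25\,z(-\log \text{sway}) + 0.22\,z(-\text{droop}) +
0.69\,z(\mathrm{DT})$ rescaled to [0, 1], plus independent Gaussian rater
noise (sd 0.08 on that scale, about half a Likert point), rounded onto
1–7. The weights mirror the 60 s standardized coefficients the regression
is expected to recover. `simulate_rating_table()` generates directly at
the index level (independent standard-normal predictors, standardized
generating weights, unit response variance) for studying the regression in
isolation.

What the generator does **not** emulate: correlated detector errors,
identity switches or left/right swaps, perspective and lens effects,
trunk/compensatory movement beyond the extended limbs, and any real child
kinematics. Tests passing on synthetic cohorts therefore establish the
pipeline's arithmetic and its monotone links, not clinical validity on
real videos.

## Problem sizes

The shipped tests and examples use 10 fps synthetic cohorts of 68 trials
(and a handful of 5 fps mini-cohorts for the IO round trips), 500-trial
rating tables for parameter recovery, and 50-replicate truncation
comparisons; those sizes give stable statistics for every check while the
whole suite runs in well under a minute. All of them are ordinary function
arguments, so larger cohorts or full 30 fps trials only cost proportional
time.

## A worked run

```{r, eval = FALSE}
library(birddogcv)
co <- generate_cohort(cohort_config(fps = 10, master_seed = 11))
idx <- score_cohort(co$recordings)
idx$TQCE <- co$tqce

spearman_cor(idx$SPB, idx$TQCE)
fit_cv <- fit_tqce(idx)                      # SPB + AG + DT
fit_dt <- fit_tqce(idx, predictors = "DT_s") # DT only
summary(fit_cv)
predicted_correlation(fit_dt, idx)
truncate_and_reanalyze(co$recordings, co$tqce, times = seq(10, 60, 10))
icc_2_1(co$ratings)
```

The same flow is scriptable from a shell via the thin wrapper in
`inst/cli/birddog.R` (`simulate`, `score`, `analyze` subcommands over a
YAML run configuration).

## Known limitations

* The heuristic DT mode assumes a horizontal floor visible as the lowest
  supporting-keypoint position; slanted cameras need the floor line
  overridden.
* SPB and AG are cohort-relative z-scores: a trial's value changes with
  the cohort it is standardized in, and a single trial cannot be scored
  alone.
* The angle score treats raising and lowering symmetrically by
  construction; it cannot distinguish the two.
* 2D sagittal geometry only: out-of-plane motion projects onto the image
  plane and is under- or over-counted accordingly.
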