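# birddogcv

Computer-vision indices of postural control for the bird-dog
(one-arm-and-one-leg balance) task, computed from 2D pose-estimation
keypoints.

## The problem

Pediatric occupational therapists score the bird-dog task — hold a
four-point crawling posture with one arm and the contralateral leg lifted,
up to 60 s per side — by a single number: the duration time (DT) until a
lifted limb touches the floor. That misses what therapists actually watch:
postural steadiness and how well the limbs are held against gravity.
`birddogcv` extracts those qualities from the BODY_25 keypoint stream a
markerless pose estimator (e.g. OpenPose) emits for a sagittal-plane
video, and provides the statistics needed to validate them against
therapist ratings. Intended users: movement-analysis researchers and
clinician-scientists working with keypoint recordings of balance tasks.

## The indices

With `p_i` a keypoint's image position in frame `i` and `bl` the mean
neck-to-mid-hip distance (the body-size/camera-distance normalizer):

* **DT** — `(fall_frame − start_frame) / fps`, capped at 60 s.
* **SPB** (static postural balance) — per extended-limb keypoint
  (wrist, elbow, ankle, knee),
  `D = (1/(n−1)) Σ ‖p_i − p_{i−1}‖ / bl`; the four are averaged into `D′`
  and `SPB = (log(1/D′) − μ) / σ`, z-scored over the cohort. High SPB =
  steady.
* **AG** (antigravity posture) — per frame, `φ` and `θ` are the absolute
  angles between the floor and the arm vector (neck → mean of wrist and
  elbow) and leg vector (mid-hip → mean of ankle and knee);
  `a = −(1/n) Σ (|φ| + |θ|)`, and AG is the cohort z-score of `a`. High
  AG = limbs held horizontal.

Keypoints with confidence < 0.5 are masked and linearly interpolated
before any index. Validation tooling: Spearman correlations with mean
therapist ratings (TQCE), standardized-beta regression comparing a DT-only
model with SPB+AG+DT (`fit_tqce()`), test-time truncation curves
(`truncate_and_reanalyze()`), ICC(2,1) interrater reliability
(`icc_2_1()`), and a deterministic synthetic-cohort simulator with known
ground truth (`generate_cohort()`), since no real videos ship with the
package.

## Worked example

Simulate a 68-trial cohort (34 participants × two sides, 10 fps), score
it, and run the validation analyses:

```r
library(birddogcv)
co  <- generate_cohort(cohort_config(fps = 10, master_seed = 11))
idx <- score_cohort(co$recordings)
idx$TQCE <- co$tqce

head(idx[c("participant_id", "side", "DT_s", "D_prime", "a_raw", "SPB", "AG", "TQCE")], 3)
#>   participant_id           side DT_s     D_prime     a_raw        SPB         AG     TQCE
#> 1           P001  left_extended 49.1 0.007342911 -11.18896  0.4460415  1.0745795 5.333333
#> 2           P001 right_extended 20.8 0.003566962 -34.92181  1.5065316 -0.5913917 4.000000
#> 3           P002  left_extended  2.0 0.032441107 -42.95100 -1.7361120 -1.1550154 2.000000

spearman_cor(idx$SPB, idx$TQCE)   # rs = 0.670, p = 4.2e-10
spearman_cor(idx$AG,  idx$TQCE)   # rs = 0.341, p = 0.0045

summary(fit_tqce(idx))            # SPB + AG + DT model
#> Standardized regression of TQCE (n = 68)
#>  predictor  beta     se beta_raw  se_raw
#>        SPB 0.277 0.0390   0.4186 0.05899
#>         AG 0.346 0.0312   0.5236 0.04722
#>       DT_s 0.709 0.0390   0.0525 0.00289
#> R^2 = 0.938, adjusted R^2 = 0.935
#> Spearman(fitted, TQCE): rs = 0.970, p = 2.47e-42

predicted_correlation(fit_tqce(idx, predictors = "DT_s"), idx)$rs  # 0.882

truncate_and_reanalyze(co$recordings, co$tqce, times = c(20, 40, 60))
#>   time_s      r_cv         p_cv      r_dt         p_dt
#> 1     20 0.7983226 3.540816e-16 0.7270602 2.211973e-12
#> 2     40 0.9399965 1.562460e-32 0.8783019 7.827652e-23
#> 3     60 0.9701530 2.474695e-42 0.8819094 3.077168e-23

icc_2_1(co$ratings)               # 0.885
```

Reading the output: the steadiness index correlates strongly with the
simulated therapist ratings and the droop index more weakly; adding both
to DT raises the fitted-vs-rating correlation from 0.882 to 0.970 at the
full 60 s, and the gap widens when the test is truncated to 20 s
(0.798 vs 0.727) — shorter testing loses less information when the
vision-based indices are included. ICC(2,1) = 0.885 says the three
simulated raters agree about as well as trained clinicians typically do.

A shell interface wrapping the same functions (subcommands `simulate`,
`score`, `analyze` over a YAML config) is installed at
`inst/cli/birddog.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "birddog.R", package = "birddogcv"))')" \
  simulate --data-dir data --out-dir report --seed 21
```

See `vignettes/quantifying-postural-control.Rmd` for the model details,
parameter meanings, the synthetic generator's scope, and known
limitations.

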