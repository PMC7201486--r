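# The three per-trial indices: duration time (DT), static postural balance
# (SPB) and antigravity posture (AG), with cohort-level standardization.

#' Mean per-frame moving distance of a keypoint, in body lengths
#'
#' For an interpolated trajectory with frames `p_0 ... p_{n-1}`,
#' `D = (1/(n-1)) * sum_i ||p_i - p_{i-1}|| / bl`: the Euclidean step
#' between consecutive frames, normalized by the body length and averaged
#' over the frame direction. Translation-invariant; the body-length divisor
#' makes it invariant under uniform scaling of the scene.
#'
#' @param traj an interpolated `trajectory` (or an `n x 2` coordinate
#'   matrix), `n >= 2`.
#' @param bl body length in pixels (see [body_length()]).
#' @return `D` in body lengths/frame, `>= 0`.
#' @export
moving_distance <- function(traj, bl) {
  xy <- if (inherits(traj, "trajectory")) traj_xy(traj) else as.matrix(traj)
  n <- nrow(xy)
  if (n < 2L) {
    bd_stop("too_short_error", "moving_distance needs >= 2 frames, got %d", n)
  }
  steps <- sqrt(rowSums(diff(xy)^2))
  sum(steps) / ((n - 1) * bl)
}

#' Combine the four extended-limb moving distances
#'
#' `D' = (D_w + D_e + D_a + D_k) / 4` over the wrist and elbow of the
#' extended arm and the ankle and knee of the extended leg.
#'
#' @param d_w,d_e,d_a,d_k moving distances (body lengths/frame, `>= 0`).
#' @return `D'`.
#' @export
combined_distance <- function(d_w, d_e, d_a, d_k) {
  (d_w + d_e + d_a + d_k) / 4
}

cohort_zscore <- function(v, what) {
  if (length(v) < 2L) {
    bd_stop("constant_cohort_error",
            "standardizing %s needs >= 2 trials, got %d", what, length(v))
  }
  s <- stats::sd(v)   # sample sd, n - 1
  if (!is.finite(s) || s == 0) {
    bd_stop("constant_cohort_error",
            "%s is constant across the cohort; z-scores undefined", what)
  }
  (v - mean(v)) / s
}

#' Static postural balance z-scores for a cohort
#'
#' `SPB_j = (log(1/D'_j) - mu) / sigma`, where `mu` and `sigma` are the mean
#' and sample standard deviation of `log(1/D')` across the cohort's trials
#' (natural log). Low movement gives high SPB; by construction the cohort
#' SPB has mean 0 and sample sd 1. Each `D'` is floored at `d_prime_floor`
#' before the log so a perfectly stationary trial cannot produce `log(1/0)`.
#'
#' @param d_prime per-trial `D'` values (length >= 2).
#' @param d_prime_floor floor applied before the log (default 1e-6).
#' @return per-trial SPB z-scores.
#' @export
spb_standardize <- function(d_prime, d_prime_floor = 1e-6) {
  s <- log(1 / pmax(d_prime, d_prime_floor))
  cohort_zscore(s, "log(1/D')")
}

#' Antigravity posture z-scores for a cohort
#'
#' The z-score of the raw antigravity score `a` (see [ag_raw()]) across the
#' cohort, with the sample standard deviation. High AG means the extended
#' limbs were held close to horizontal against gravity.
#'
#' @param a_raw per-trial raw scores in degrees (`<= 0`), length >= 2.
#' @return per-trial AG z-scores.
#' @export
ag_standardize <- function(a_raw) {
  cohort_zscore(a_raw, "antigravity score a")
}

#' Absolute limb-floor angle
#'
#' The floor is assumed parallel to the image's horizontal axis, so the
#' angle between a limb vector and the floor is
#' `atan(|dy| / |dx|)` in degrees, in `[0, 90]`. Taking absolute values
#' means raising and lowering the limb give the same angle. A vertical limb
#' (`dx = 0`) returns 90.
#'
#' @param origin,tip limb vector endpoints: length-2 `(x, y)` vectors or
#'   `n x 2` matrices (vectorized over frames).
#' @return angle(s) in degrees.
#' @export
limb_angle <- function(origin, tip) {
  o <- if (is.matrix(origin)) origin else matrix(origin, ncol = 2)
  t_ <- if (is.matrix(tip)) tip else matrix(tip, ncol = 2)
  dx <- abs(t_[, 1] - o[, 1])
  dy <- abs(t_[, 2] - o[, 2])
  degen <- dx == 0 & dy == 0
  if (any(degen)) {
    bd_stop("degenerate_limb_error",
            "limb origin and tip coincide at frame %d", which(degen)[1] - 1L)
  }
  ifelse(dx == 0, 90, atan(dy / dx) * 180 / pi)
}

#' Raw antigravity score of a trial
#'
#' Per frame, the arm vector runs from the neck to the mean position of the
#' extended arm's wrist and elbow, and the leg vector from the mid-hip to
#' the mean position of the extended leg's ankle and knee. With `phi` and
#' `theta` the absolute angles of these vectors to the floor,
#' `a = -(1/n) * sum(|phi| + |theta|)`, in degrees, `<= 0`. Perfectly
#' horizontal limbs score the maximum, 0; both drooping and over-raising
#' lower the score.
#'
#' @param prep preprocessed trial from [preprocess_trial()] (interpolated
#'   trajectories for neck, mid-hip and the extended limb keypoints).
#' @return `a` in degrees.
#' @export
ag_raw <- function(prep) {
  ext <- extended_keypoints(prep$side)
  tr <- prep$traj
  arm_tip <- (traj_xy(tr[[ext$wrist]]) + traj_xy(tr[[ext$elbow]])) / 2
  leg_tip <- (traj_xy(tr[[ext$ankle]]) + traj_xy(tr[[ext$knee]])) / 2
  phi <- limb_angle(traj_xy(tr[["Neck"]]), arm_tip)
  theta <- limb_angle(traj_xy(tr[["MidHip"]]), leg_tip)
  -mean(abs(phi) + abs(theta))
}

# Heuristic detection of posture onset and floor contact from keypoints.
# Returns 0-based ordinals: list(start, fall (NULL if none), floor_y).
detect_posture_events <- function(recording, config, prep = NULL) {
  prep <- prep %||% preprocess_trial(recording,
                                     threshold = config$confidence_threshold)
  ext <- extended_keypoints(recording$side)
  tr <- prep$traj
  bl <- prep$bl
  # Floor line: the lowest image point reached by the supporting wrist and
  # ankle over the trial (y grows downward).
  floor_y <- max(tr[[ext$support_wrist]]$y, tr[[ext$support_ankle]]$y)
  wrist_y <- tr[[ext$wrist]]$y
  ankle_y <- tr[[ext$ankle]]$y
  arm_tip <- (traj_xy(tr[[ext$wrist]]) + traj_xy(tr[[ext$elbow]])) / 2
  leg_tip <- (traj_xy(tr[[ext$ankle]]) + traj_xy(tr[[ext$knee]])) / 2
  phi <- limb_angle(traj_xy(tr[["Neck"]]), arm_tip)
  theta <- limb_angle(traj_xy(tr[["MidHip"]]), leg_tip)
  lifted <- wrist_y < floor_y - config$lift_margin_bl * bl &
    ankle_y < floor_y - config$lift_margin_bl * bl &
    phi < config$extension_angle_max & theta < config$extension_angle_max
  if (!any(lifted)) {
    bd_stop("no_posture_error",
            "trial %s: extended posture never detected",
            recording$participant_id)
  }
  start <- which(lifted)[1]                 # 1-based
  contact <- wrist_y >= floor_y - config$floor_margin_bl * bl |
    ankle_y >= floor_y - config$floor_margin_bl * bl
  after <- which(contact & seq_along(contact) > start)
  list(start = start - 1L,
       fall = if (length(after)) after[1] - 1L,
       floor_y = floor_y)
}

#' Duration time of a trial, in seconds
#'
#' The seconds the bird-dog posture was maintained before any extended limb
#' touched the floor, capped at the task maximum (`task_cap_s`, default
#' 60 s): `DT = (fall_frame - start_frame) / fps`. If the posture is held
#' without floor contact to the end of the recording, DT is the (capped)
#' remaining recording length, so a full-length recording scores the cap.
#'
#' Two modes: `"annotated"` uses the recording's annotated start/fall
#' frames; `"heuristic"` detects posture onset (extended wrist and ankle
#' clear of the floor line, both limb angles small) and first floor contact
#' from the keypoints themselves.
#'
#' @param recording a [trial_recording()].
#' @param mode `"annotated"` or `"heuristic"`; defaults to `config$dt_mode`.
#' @param config a [birddog_config()].
#' @return DT in seconds, in `[0, task_cap_s]`.
#' @export
duration_time <- function(recording, mode = NULL, config = birddog_config()) {
  mode <- match.arg(mode %||% config$dt_mode, c("annotated", "heuristic"))
  n <- n_frames(recording)
  if (mode == "annotated") {
    start <- recording$annotated_start_frame %||% 0L
    fall <- recording$annotated_fall_frame
    if (!is.null(fall) && fall < start) {
      bd_stop("metadata_error",
              "trial %s: annotated fall frame %d precedes start frame %d",
              recording$participant_id, fall, start)
    }
  } else {
    ev <- detect_posture_events(recording, config)
    start <- ev$start
    fall <- ev$fall
  }
  dt <- if (is.null(fall)) (n - start) / recording$fps
  else (fall - start) / recording$fps
  min(max(dt, 0), config$task_cap_s)
}

# 0-based ordinal of the last frame in the analysis window: the fall frame
# if one is known (annotated, or detected in heuristic mode), the task cap,
# or the recording end, whichever comes first. window_s further truncates
# the test time (used by truncate_and_reanalyze).
analysis_window <- function(recording, config, window_s = NULL) {
  n <- n_frames(recording)
  start <- recording$annotated_start_frame %||% 0L
  t_cap <- min(window_s %||% config$task_cap_s, config$task_cap_s)
  end <- n - 1L
  fall <- recording$annotated_fall_frame
  if (config$dt_mode == "heuristic") {
    ev <- detect_posture_events(recording, config)
    start <- ev$start
    fall <- ev$fall
  }
  if (!is.null(fall)) end <- min(end, fall)
  end <- min(end, start + round(t_cap * recording$fps))
  c(start = start, end = max(end, start + 1L))
}

#' Score one trial: raw indices before cohort standardization
#'
#' Computes DT and the raw movement and angle quantities over the trial's
#' analysis window (start frame through fall frame, capped at the task
#' maximum; frames after a fall are excluded). SPB and AG require a cohort
#' and are added by [score_cohort()].
#'
#' @param recording a [trial_recording()].
#' @param config a [birddog_config()].
#' @param window_s optional truncated test time in seconds (frames beyond
#'   `min(fall, window_s)` are discarded and DT is capped at `window_s`).
#' @return one-row data frame: `participant_id, side, DT_s, D_w, D_e, D_a,
#'   D_k, D_prime, a_raw`.
#' @export
score_trial <- function(recording, config = birddog_config(), window_s = NULL) {
  win <- analysis_window(recording, config, window_s)
  prep <- preprocess_trial(recording,
                           threshold = config$confidence_threshold,
                           frame_range = c(win["start"] + 1L, win["end"] + 1L))
  ext <- extended_keypoints(recording$side)
  bl <- prep$bl
  d_w <- moving_distance(prep$traj[[ext$wrist]], bl)
  d_e <- moving_distance(prep$traj[[ext$elbow]], bl)
  d_a <- moving_distance(prep$traj[[ext$ankle]], bl)
  d_k <- moving_distance(prep$traj[[ext$knee]], bl)
  dt <- duration_time(recording, config = config)
  if (!is.null(window_s)) dt <- min(dt, window_s)
  data.frame(participant_id = recording$participant_id,
             side = recording$side,
             DT_s = dt,
             D_w = d_w, D_e = d_e, D_a = d_a, D_k = d_k,
             D_prime = combined_distance(d_w, d_e, d_a, d_k),
             a_raw = ag_raw(prep),
             stringsAsFactors = FALSE)
}

#' Score a cohort of trials and standardize SPB and AG
#'
#' Scores every recording with [score_trial()] and adds the cohort-level
#' z-scores: `SPB` from `log(1/D')` and `AG` from the raw antigravity score.
#' The standardization cohort is all supplied trials (participant x side).
#'
#' @param recordings list of [trial_recording()] objects.
#' @param config a [birddog_config()].
#' @param window_s optional truncated test time (see [score_trial()]).
#' @return data frame with one row per trial: the [score_trial()] columns
#'   plus `SPB` and `AG`.
#' @export
score_cohort <- function(recordings, config = birddog_config(),
                         window_s = NULL) {
  rows <- lapply(recordings, score_trial, config = config,
                 window_s = window_s)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$SPB <- spb_standardize(df$D_prime, config$d_prime_floor)
  df$AG <- ag_standardize(df$a_raw)
  df
}
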