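# Synthetic bird-dog recordings and simulated therapist ratings with known
# ground truth, so every pipeline stage is testable without real videos.

#' Parameters for one synthetic trial
#'
#' @param sway_sigma per-frame Gaussian step sd of the extended-limb
#'   keypoints, in body lengths/frame (mean-reverting sway; default 0.005).
#' @param droop_deg mean deviation of each extended limb from horizontal, in
#'   degrees (default 10).
#' @param fall_time_s seconds until the extended wrist and ankle drop to the
#'   floor line, or `NULL` for no fall (default).
#' @param dropout_rate per-keypoint, per-frame probability of a
#'   below-threshold confidence (default 0.02), in `[0, 1)`.
#' @param fps frame rate (default 30).
#' @param duration_s recording length in seconds; defaults to 2 s past the
#'   fall, or 62 s (the task cap plus a margin) when there is no fall.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return a `trial_params` list.
#' @export
trial_params <- function(sway_sigma = 0.005, droop_deg = 10,
                         fall_time_s = NULL, dropout_rate = 0.02,
                         fps = 30, duration_s = NULL, seed = 1L) {
  stopifnot(sway_sigma >= 0, droop_deg >= 0,
            dropout_rate >= 0, dropout_rate < 1, fps > 0)
  if (is.null(duration_s)) {
    duration_s <- if (is.null(fall_time_s)) 62 else min(fall_time_s + 2, 62)
  }
  structure(list(sway_sigma = sway_sigma, droop_deg = droop_deg,
                 fall_time_s = fall_time_s, dropout_rate = dropout_rate,
                 fps = fps, duration_s = duration_s, seed = as.integer(seed)),
            class = "trial_params")
}

# Static skeleton template in the canonical (participant-horizontal)
# orientation, head to the left, floor below. Roles, not sides: the caller
# maps roles onto L/R keypoint names according to the trial side.
skeleton_template <- function(L, image_width, image_height) {
  W <- image_width
  H <- image_height
  neck <- c(W / 2 - L / 2, 0.53 * H)
  hip <- c(W / 2 + L / 2, 0.53 * H)
  floor_y <- neck[2] + 0.9 * L
  list(
    neck = neck, hip = hip, floor_y = floor_y,
    nose = neck + c(-0.25 * L, -0.08 * L),
    eye = neck + c(-0.28 * L, -0.12 * L),
    ear = neck + c(-0.20 * L, -0.12 * L),
    sup_elbow = c(neck[1], (neck[2] + floor_y) / 2),
    sup_wrist = c(neck[1], floor_y),
    sup_knee = c(hip[1] + 0.10 * L, floor_y),
    sup_ankle = c(hip[1] + 0.45 * L, floor_y),
    ext_elbow_r = 0.40 * L,   # radial distances along the extended limbs
    ext_wrist_r = 0.80 * L,
    ext_knee_r = 0.425 * L,
    ext_ankle_r = 0.85 * L
  )
}

#' Generate one synthetic bird-dog trial
#'
#' Emulates a sagittal-plane keypoint recording of the bird-dog posture: a
#' fixed skeleton with the supporting wrist, knee and ankle on the floor
#' line, the extended arm and contralateral leg held at `droop_deg` below
#' horizontal with mean-reverting Gaussian sway, an optional fall event
#' after which the extended wrist and ankle rest on the floor, and
#' detection confidences with a controllable dropout fraction below the
#' masking threshold. Deterministic given `params$seed`.
#'
#' @param params a [trial_params()].
#' @param side which arm is lifted (default `"left_extended"`).
#' @param participant_id participant label.
#' @param image_width,image_height frame dimensions in pixels.
#' @param body_length_px neck-to-hip distance of the template, px.
#' @return list with `recording` (a [trial_recording()], annotated with the
#'   fall frame when one occurs) and `truth` (one-row data frame of
#'   generating parameters and the true duration time).
#' @export
generate_trial <- function(params, side = "left_extended",
                           participant_id = "sim",
                           image_width = 1280L, image_height = 720L,
                           body_length_px = 200) {
  side <- match.arg(side, task_sides)
  n <- max(2L, round(params$duration_s * params$fps))
  L <- body_length_px
  tpl <- skeleton_template(L, image_width, image_height)
  ext <- extended_keypoints(side)
  kp_names <- body25_keypoints()

  base <- matrix(NA_real_, 25L, 2L, dimnames = list(kp_names, c("x", "y")))
  delta <- params$droop_deg * pi / 180
  arm_dir <- c(-cos(delta), sin(delta))   # forward past the head, y down
  leg_dir <- c(cos(delta), sin(delta))    # backward past the hip
  base["Nose", ] <- tpl$nose
  base["Neck", ] <- tpl$neck
  base["MidHip", ] <- tpl$hip
  base[c("REye", "LEye"), ] <- rep(tpl$eye, each = 2)
  base[c("REar", "LEar"), ] <- rep(tpl$ear, each = 2)
  base[c("RShoulder", "LShoulder"), ] <-
    rep(tpl$neck + c(0.03 * L, 0.02 * L), each = 2)
  base[c("RHip", "LHip"), ] <- rep(tpl$hip + c(0, 0.02 * L), each = 2)
  # supporting limbs, on/above the floor line
  sup_arm <- setdiff(c("RElbow", "LElbow"), ext$elbow)
  base[sup_arm, ] <- tpl$sup_elbow
  base[ext$support_wrist, ] <- tpl$sup_wrist
  base[ext$support_knee, ] <- tpl$sup_knee
  base[ext$support_ankle, ] <- tpl$sup_ankle
  # extended limbs at the droop angle
  base[ext$elbow, ] <- tpl$neck + tpl$ext_elbow_r * arm_dir
  base[ext$wrist, ] <- tpl$neck + tpl$ext_wrist_r * arm_dir
  base[ext$knee, ] <- tpl$hip + tpl$ext_knee_r * leg_dir
  base[ext$ankle, ] <- tpl$hip + tpl$ext_ankle_r * leg_dir
  # feet near their ankles
  ext_foot <- if (ext$ankle == "RAnkle") c("RBigToe", "RSmallToe", "RHeel")
  else c("LBigToe", "LSmallToe", "LHeel")
  sup_foot <- setdiff(c("RBigToe", "RSmallToe", "RHeel",
                        "LBigToe", "LSmallToe", "LHeel"), ext_foot)
  base[ext_foot, ] <- rep(base[ext$ankle, ] + c(0.08 * L, 0), each = 3)
  base[sup_foot, ] <- rep(base[ext$support_ankle, ] + c(0.12 * L, 0), each = 3)

  fall_frame <- if (!is.null(params$fall_time_s)) {
    ff <- round(params$fall_time_s * params$fps)
    if (ff < n) as.integer(ff) else NULL
  }

  arr <- with_seed(params$seed, {
    a <- array(rep(as.vector(cbind(base, 0)), each = n), c(n, 25L, 3L),
               dimnames = list(NULL, kp_names, c("x", "y", "confidence")))
    # mean-reverting sway on the extended-limb keypoints
    s <- params$sway_sigma * L
    rho <- 0.95
    sway_kp <- c(ext$wrist, ext$elbow, ext$ankle, ext$knee)
    for (kp in sway_kp) {
      for (coord in c("x", "y")) {
        off <- if (s > 0) {
          as.numeric(stats::filter(stats::rnorm(n, 0, s), rho,
                                   method = "recursive"))
        } else numeric(n)
        a[, kp, coord] <- a[, kp, coord] + off
      }
    }
    # fall: extended wrist/ankle drop to the floor, posture ends
    if (!is.null(fall_frame)) {
      post <- (fall_frame + 1L):n     # 1-based rows at/after the fall ordinal
      a[post, ext$wrist, "y"] <- tpl$floor_y
      a[post, ext$ankle, "y"] <- tpl$floor_y
      a[post, ext$wrist, "x"] <- base[ext$wrist, "x"]
      a[post, ext$ankle, "x"] <- base[ext$ankle, "x"]
      a[post, ext$elbow, "y"] <- (tpl$neck[2] + tpl$floor_y) / 2
      a[post, ext$knee, "y"] <- (tpl$hip[2] + tpl$floor_y) / 2
    }
    conf <- matrix(stats::runif(n * 25L, 0.6, 0.95), n, 25L)
    if (params$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * 25L) < params$dropout_rate, n, 25L)
      conf[drop] <- stats::runif(sum(drop), 0.05, 0.45)
    }
    a[, , "confidence"] <- conf
    a
  })

  recording <- trial_recording(
    arr, side = side, fps = params$fps, participant_id = participant_id,
    image_width = image_width, image_height = image_height,
    annotated_start_frame = 0L, annotated_fall_frame = fall_frame
  )
  truth <- data.frame(
    participant_id = participant_id, side = side,
    sway_sigma = params$sway_sigma, droop_deg = params$droop_deg,
    fall_time_s = params$fall_time_s %||% NA_real_,
    dropout_rate = params$dropout_rate,
    dt_true = min(params$fall_time_s %||% params$duration_s, 60),
    seed = params$seed, stringsAsFactors = FALSE
  )
  list(recording = recording, truth = truth)
}

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study design this package emulates: 34 participants
#' performing the task once per side (68 trials) and three raters on a
#' 7-point scale. Per-trial parameters are drawn from uniform ranges, except
#' the fall time, which is lognormal with roughly a quarter of trials
#' lasting the full 60 s cap (no fall) and roughly half reaching 20 s.
#'
#' @param n_participants number of participants (default 34).
#' @param sides_per_participant trials per participant (default 2, one per
#'   side).
#' @param rater_count simulated raters (default 3).
#' @param rater_noise_sd sd of each rater's independent noise on the latent
#'   quality scale `[0, 1]` (default 0.08, about half a Likert point).
#' @param quality_weights weights `(w_spb, w_ag, w_dt)` combining the
#'   z-scored generating parameters into the latent quality driving the
#'   ratings (default `c(0.25, 0.22, 0.69)`).
#' @param fps,image_width,image_height,body_length_px recording geometry.
#' @param sway_range,droop_range,dropout_range uniform ranges for the
#'   per-trial generating parameters.
#' @param fall_meanlog,fall_sdlog lognormal fall-time parameters (seconds);
#'   draws at or past the cap become no-fall trials.
#' @param task_cap_s task maximum (default 60 s).
#' @param master_seed seed for the whole cohort; per-trial child seeds are
#'   derived from it by a fixed counter scheme.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 34, sides_per_participant = 2,
                          rater_count = 3, rater_noise_sd = 0.08,
                          quality_weights = c(spb = 0.25, ag = 0.22, dt = 0.69),
                          fps = 30, image_width = 1280L, image_height = 720L,
                          body_length_px = 200,
                          sway_range = c(0.001, 0.015),
                          droop_range = c(0, 28),
                          dropout_range = c(0, 0.08),
                          fall_meanlog = log(24), fall_sdlog = 1.2,
                          task_cap_s = 60, master_seed = 1L) {
  stopifnot(n_participants >= 2, rater_count >= 2)
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with ratings and ground truth
#'
#' Draws per-trial generating parameters, builds every recording with
#' [generate_trial()] (child-seeded from the master seed, so each trial is
#' independently reproducible), and simulates the therapist ratings: a
#' latent quality
#' `q = w_spb * z(-log sway) + w_ag * z(-droop) + w_dt * z(DT_true)`
#' rescaled to `[0, 1]`, to which each rater adds independent Gaussian noise
#' before rounding onto the 1-7 Likert scale.
#'
#' @param config a [cohort_config()].
#' @return list with `recordings` (list of [trial_recording()]), `truth`
#'   (data frame incl. the latent `quality`), `ratings` (trials x raters
#'   integer matrix) and `tqce` (row means of `ratings`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  n_trials <- config$n_participants * config$sides_per_participant
  sides <- rep(rep_len(task_sides, config$sides_per_participant),
               times = config$n_participants)
  pids <- sprintf("P%03d", rep(seq_len(config$n_participants),
                               each = config$sides_per_participant))
  drawn <- with_seed(config$master_seed, {
    sway <- stats::runif(n_trials, config$sway_range[1], config$sway_range[2])
    droop <- stats::runif(n_trials, config$droop_range[1], config$droop_range[2])
    dropout <- stats::runif(n_trials, config$dropout_range[1],
                            config$dropout_range[2])
    fall_raw <- stats::rlnorm(n_trials, config$fall_meanlog, config$fall_sdlog)
    eps <- matrix(stats::rnorm(n_trials * config$rater_count, 0,
                               config$rater_noise_sd),
                  n_trials, config$rater_count)
    list(sway = sway, droop = droop, dropout = dropout,
         fall = ifelse(fall_raw >= config$task_cap_s, NA_real_, fall_raw),
         eps = eps)
  })
  child_seed <- as.integer((as.numeric(config$master_seed) +
                              104729 * seq_len(n_trials)) %% 2147483647) + 1L
  trials <- vector("list", n_trials)
  truth <- vector("list", n_trials)
  for (j in seq_len(n_trials)) {
    p <- trial_params(sway_sigma = drawn$sway[j], droop_deg = drawn$droop[j],
                      fall_time_s = if (!is.na(drawn$fall[j])) drawn$fall[j],
                      dropout_rate = drawn$dropout[j], fps = config$fps,
                      seed = child_seed[j])
    g <- generate_trial(p, side = sides[j], participant_id = pids[j],
                        image_width = config$image_width,
                        image_height = config$image_height,
                        body_length_px = config$body_length_px)
    trials[[j]] <- g$recording
    truth[[j]] <- g$truth
  }
  truth <- do.call(rbind, truth)
  truth$trial_id <- sprintf("%s_%s", truth$participant_id, truth$side)
  w <- config$quality_weights
  z <- function(v) {
    if (stats::sd(v) == 0) {
      warning("degenerate cohort: a generating parameter is constant")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / stats::sd(v)
  }
  q <- w[1] * z(-log(truth$sway_sigma)) + w[2] * z(-truth$droop_deg) +
    w[3] * z(truth$dt_true)
  if (max(q) > min(q)) q <- (q - min(q)) / (max(q) - min(q))
  ratings <- round(1 + 6 * (q + drawn$eps))
  ratings[ratings < 1] <- 1
  ratings[ratings > 7] <- 7
  dimnames(ratings) <- list(truth$trial_id,
                            sprintf("r%d", seq_len(config$rater_count)))
  truth$quality <- q
  list(recordings = trials, truth = truth, ratings = ratings,
       tqce = rowMeans(ratings))
}

#' Simulate a rating table at the regression level
#'
#' Generates a cohort table directly on the index scale, for studying the
#' standardized regression in isolation: independent standard-normal
#' predictors and
#' `TQCE = w_spb * SPB + w_ag * AG + w_dt * DT_s + noise`. The default
#' noise sd makes the response variance approximately 1, so the generating
#' weights are recovered as standardized betas.
#'
#' @param n number of trials.
#' @param weights generating standardized weights, named after the
#'   predictor columns (default `c(SPB = 0.25, AG = 0.22, DT_s = 0.69)`).
#' @param noise_sd residual sd; default `sqrt(1 - sum(weights^2))`.
#' @param seed RNG seed.
#' @return data frame with columns `SPB`, `AG`, `DT_s`, `TQCE`.
#' @export
simulate_rating_table <- function(n = 500,
                                  weights = c(SPB = 0.25, AG = 0.22, DT_s = 0.69),
                                  noise_sd = NULL, seed = 1L) {
  noise_sd <- noise_sd %||% sqrt(max(1e-6, 1 - sum(weights^2)))
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * length(weights)), n, length(weights),
                dimnames = list(NULL, names(weights)))
    df <- as.data.frame(X)
    df$TQCE <- as.numeric(X %*% weights) + stats::rnorm(n, 0, noise_sd)
    df
  })
}

#' Write a synthetic cohort to disk in the OpenPose dialect
#'
#' One directory of per-frame JSON files per trial, plus `metadata.csv`
#' (trial id, side, fps, geometry, annotated fall frame), `ratings.csv`
#' (per-rater scores and their mean) and `truth.csv` (generating
#' parameters).
#'
#' @param cohort result of [generate_cohort()].
#' @param directory output directory.
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  meta <- vector("list", length(cohort$recordings))
  for (j in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[j]]
    tid <- cohort$truth$trial_id[j]
    write_openpose_trial(rec, file.path(directory, tid), trial_id = tid)
    meta[[j]] <- data.frame(
      trial_id = tid, participant_id = rec$participant_id, side = rec$side,
      fps = rec$fps, image_width = rec$image_width,
      image_height = rec$image_height, n_frames = n_frames(rec),
      annotated_start_frame = rec$annotated_start_frame,
      annotated_fall_frame = rec$annotated_fall_frame %||% NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(do.call(rbind, meta), file.path(directory, "metadata.csv"),
                   row.names = FALSE)
  ratings <- data.frame(trial_id = rownames(cohort$ratings),
                        cohort$ratings, TQCE = cohort$tqce,
                        row.names = NULL, stringsAsFactors = FALSE)
  utils::write.csv(ratings, file.path(directory, "ratings.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(directory, "truth.csv"),
                   row.names = FALSE)
  invisible(directory)
}

#' Load a cohort written by [write_cohort()]
#'
#' @param directory the cohort directory.
#' @return list with `recordings`, `metadata`, and (when present)
#'   `ratings` and `tqce`.
#' @export
load_cohort <- function(directory) {
  meta_path <- file.path(directory, "metadata.csv")
  if (!file.exists(meta_path)) {
    bd_stop("empty_trial_error", "no metadata.csv in %s", directory)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  recordings <- lapply(seq_len(nrow(meta)), function(j) {
    m <- meta[j, ]
    load_trial(file.path(directory, m$trial_id), side = m$side, fps = m$fps,
               participant_id = m$participant_id,
               image_width = m$image_width, image_height = m$image_height,
               annotated_start_frame = m$annotated_start_frame,
               annotated_fall_frame = if (!is.na(m$annotated_fall_frame))
                 m$annotated_fall_frame)
  })
  out <- list(recordings = recordings, metadata = meta)
  rat_path <- file.path(directory, "ratings.csv")
  if (file.exists(rat_path)) {
    rat <- utils::read.csv(rat_path, stringsAsFactors = FALSE)
    out$ratings <- rat
    out$tqce <- rat$TQCE
  }
  out
}
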