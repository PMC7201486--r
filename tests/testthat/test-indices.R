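test_that("moving distance matches direct summation and its invariances", {
  # stationary keypoint
  expect_equal(moving_distance(cbind(rep(3, 10), rep(4, 10)), bl = 100), 0)
  # 10 steps of 1 px over bl = 100: D = 0.01
  xy <- cbind(0:10, rep(0, 11))
  expect_equal(moving_distance(xy, bl = 100), 0.01)
  expect_equal(naive_moving_distance(xy, 100), 0.01)
  # translation invariance
  expect_equal(moving_distance(sweep(xy, 2, c(123, -456)), bl = 100), 0.01)
  expect_error(moving_distance(cbind(1, 1), bl = 100),
               class = "too_short_error")
})

test_that("vectorized D equals the naive per-frame loop on random paths", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(2:200, 1)
    xy <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
    bl <- runif(1, 10, 500)
    expect_equal(moving_distance(xy, bl), naive_moving_distance(xy, bl),
                 tolerance = 1e-12)
    # bl cancels a uniform scaling of the scene
    s <- runif(1, 0.2, 5)
    expect_equal(moving_distance(s * xy, s * bl), moving_distance(xy, bl),
                 tolerance = 1e-12)
  }
})

test_that("combined distance is the mean of the four limb distances", {
  expect_equal(combined_distance(0.01, 0.01, 0.01, 0.01), 0.01)
  expect_equal(combined_distance(0.01, 0.02, 0.03, 0.04), 0.025)
  expect_equal(combined_distance(0, 0, 0, 0), 0)
})

test_that("SPB standardization matches the hand-computed oracle", {
  # D' = (e^-1, e^-3) gives s = (1, 3): mean 2, sample sd sqrt(2)
  spb <- spb_standardize(c(exp(-1), exp(-3)))
  expect_equal(spb, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # a zero D' is floored, not a crash
  expect_silent(spb_standardize(c(0, 0.01)))
  expect_equal(spb_standardize(c(0, 0.01))[1],
               spb_standardize(c(1e-6, 0.01))[1])
  expect_error(spb_standardize(c(0.01, 0.01)), class = "constant_cohort_error")
  expect_error(spb_standardize(0.01), class = "constant_cohort_error")
})

test_that("SPB and AG z-scores have mean 0, sd 1, and preserve rank order", {
  set.seed(13)
  for (i in 1:10) {
    d <- runif(sample(5:60, 1), 0.001, 0.05)
    spb <- spb_standardize(d)
    expect_equal(mean(spb), 0, tolerance = 1e-12)
    expect_equal(sd(spb), 1, tolerance = 1e-12)
    # strictly decreasing in D': steadier trials score higher
    expect_equal(rank(spb), rank(-d))
    a <- -runif(length(d), 0, 120)
    ag <- ag_standardize(a)
    expect_equal(mean(ag), 0, tolerance = 1e-12)
    expect_equal(sd(ag), 1, tolerance = 1e-12)
    # strictly increasing in a: horizontal limbs score higher
    expect_equal(rank(ag), rank(a))
  }
  expect_equal(ag_standardize(c(-10, -30)), c(1, -1) / sqrt(2),
               tolerance = 1e-12)
  expect_error(ag_standardize(c(-5, -5)), class = "constant_cohort_error")
})

test_that("limb angle is the absolute angle to the horizontal floor", {
  expect_equal(limb_angle(c(0, 0), c(100, 0)), 0)
  # raised and lowered limbs give the same angle
  expect_equal(limb_angle(c(0, 0), c(100, 100)), 45)
  expect_equal(limb_angle(c(0, 0), c(100, -100)), 45)
  # arctangent oracle: atan(57.735/100) = 30 degrees
  expect_equal(limb_angle(c(0, 0), c(100, 57.735)), 30, tolerance = 1e-4)
  expect_equal(limb_angle(c(5, 5), c(5, 80)), 90)
  expect_error(limb_angle(c(1, 2), c(1, 2)), class = "degenerate_limb_error")
})

test_that("raw antigravity score averages both limb angles, negated", {
  n <- 5
  horiz <- make_prep(
    neck = cbind(rep(0, n), 0), hip = cbind(rep(200, n), 0),
    wrist = cbind(rep(-160, n), 0), elbow = cbind(rep(-80, n), 0),
    ankle = cbind(rep(370, n), 0), knee = cbind(rep(285, n), 0)
  )
  expect_equal(ag_raw(horiz), 0)
  # arm drooping 30 degrees (tip midpoint at atan(dy/dx) = 30), leg flat
  droop <- horiz
  droop$traj$LWrist$y <- rep(160 * tan(pi / 6), n)
  droop$traj$LElbow$y <- rep(80 * tan(pi / 6), n)
  expect_equal(ag_raw(droop), -30, tolerance = 1e-9)
  # raising the arm by the same angle scores the same
  raised <- horiz
  raised$traj$LWrist$y <- -droop$traj$LWrist$y
  raised$traj$LElbow$y <- -droop$traj$LElbow$y
  expect_equal(ag_raw(raised), -30, tolerance = 1e-9)
})

test_that("vectorized a equals the naive per-frame loop, and is invariant", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:50, 1)
    prep <- make_prep(
      neck = cbind(rnorm(n), rnorm(n)), hip = cbind(rnorm(n, 200), rnorm(n)),
      wrist = cbind(rnorm(n, -160), rnorm(n, 0, 30)),
      elbow = cbind(rnorm(n, -80), rnorm(n, 0, 30)),
      ankle = cbind(rnorm(n, 370), rnorm(n, 0, 30)),
      knee = cbind(rnorm(n, 285), rnorm(n, 0, 30)),
      side = sample(c("left_extended", "right_extended"), 1)
    )
    expect_equal(ag_raw(prep), naive_ag_raw(prep), tolerance = 1e-12)
    expect_lte(ag_raw(prep), 0)
    # global translation and uniform scaling leave the angles unchanged
    shifted <- prep
    shift <- runif(2, -300, 300)
    s <- runif(1, 0.3, 4)
    for (kp in names(prep$traj)) {
      shifted$traj[[kp]]$x <- s * (prep$traj[[kp]]$x + shift[1])
      shifted$traj[[kp]]$y <- s * (prep$traj[[kp]]$y + shift[2])
    }
    expect_equal(ag_raw(shifted), ag_raw(prep), tolerance = 1e-9)
  }
})

test_that("duration time applies the cap rule and annotated arithmetic", {
  # posture held for the whole >= 60 s recording: DT recorded as the cap
  long <- generate_trial(trial_params(fps = 10, duration_s = 62, seed = 2))
  expect_equal(duration_time(long$recording), 60)
  # start frame 0, fall frame 300 at 30 fps: 10 s
  fall10 <- generate_trial(trial_params(fps = 30, fall_time_s = 10, seed = 3))
  expect_equal(fall10$recording$annotated_fall_frame, 300L)
  expect_equal(duration_time(fall10$recording), 10)
  # annotated fall at the start frame: DT = 0
  rec0 <- fall10$recording
  rec0$annotated_fall_frame <- 0L
  expect_equal(duration_time(rec0), 0)
  rec_bad <- fall10$recording
  rec_bad$annotated_start_frame <- 10L
  rec_bad$annotated_fall_frame <- 5L
  expect_error(duration_time(rec_bad), class = "metadata_error")
})

test_that("duration time is within [0, cap] for random synthetic trials", {
  set.seed(31)
  for (i in 1:10) {
    fall <- if (runif(1) < 0.5) runif(1, 0.5, 80)
    g <- generate_trial(trial_params(fps = 10, fall_time_s = fall,
                                     droop_deg = runif(1, 0, 25),
                                     sway_sigma = runif(1, 0, 0.01),
                                     seed = i))
    dt <- duration_time(g$recording)
    expect_gte(dt, 0)
    expect_lte(dt, 60)
  }
})

test_that("heuristic mode detects posture onset and floor contact", {
  cfg <- birddog_config(dt_mode = "heuristic")
  g <- generate_trial(trial_params(fps = 10, fall_time_s = 8, droop_deg = 12,
                                   sway_sigma = 0.003, seed = 4))
  dt <- duration_time(g$recording, mode = "heuristic", config = cfg)
  expect_equal(dt, 8, tolerance = 0.1)
  # no fall: capped remaining recording length
  hold <- generate_trial(trial_params(fps = 10, duration_s = 62, seed = 5,
                                      droop_deg = 12, sway_sigma = 0.003))
  expect_equal(duration_time(hold$recording, "heuristic", cfg), 60)
  # extended limbs on the floor the whole time: posture never achieved
  flat <- generate_trial(trial_params(fps = 10, fall_time_s = 0,
                                      duration_s = 3, seed = 6))
  expect_error(duration_time(flat$recording, "heuristic", cfg),
               class = "no_posture_error")
})

test_that("cohort scoring attaches standardized indices", {
  set.seed(8)
  recs <- lapply(1:6, function(i) {
    generate_trial(trial_params(sway_sigma = runif(1, 0.001, 0.01),
                                droop_deg = runif(1, 2, 25),
                                fall_time_s = if (i %% 2) runif(1, 3, 50),
                                fps = 10, duration_s = 20, seed = 100 + i),
                   side = if (i %% 2) "left_extended" else "right_extended",
                   participant_id = sprintf("P%d", i))$recording
  })
  sc <- score_cohort(recs)
  expect_equal(nrow(sc), 6L)
  expect_equal(mean(sc$SPB), 0, tolerance = 1e-12)
  expect_equal(sd(sc$SPB), 1, tolerance = 1e-12)
  expect_equal(mean(sc$AG), 0, tolerance = 1e-12)
  expect_equal(sc$D_prime,
               with(sc, combined_distance(D_w, D_e, D_a, D_k)),
               tolerance = 1e-12)
  expect_true(all(sc$DT_s >= 0 & sc$DT_s <= 60))
  expect_true(all(sc$a_raw <= 0))
})
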