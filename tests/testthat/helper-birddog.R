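# Shared fixtures and independent oracles. Oracles are written as plain
# loops / enumerations so they stay independent of the vectorized package
# code they check.

# 25 x 3 keypoint matrix with constant or per-keypoint values
make_frame <- function(x = 1, y = 2, conf = 0.9) {
  matrix(c(rep_len(x, 25), rep_len(y, 25), rep_len(conf, 25)), 25, 3,
         dimnames = list(body25_keypoints(), c("x", "y", "confidence")))
}

openpose_json <- function(frames) {
  people <- lapply(frames, function(m) list(pose_keypoints_2d = as.vector(t(m))))
  jsonlite::toJSON(list(version = 1.3, people = people),
                   auto_unbox = TRUE, digits = 10)
}

# trajectory with explicit mask: masked frames get confidence 0
make_traj <- function(xs, ys = xs, mask = rep(TRUE, length(xs)), kp = "test") {
  mask_low_confidence(xs, ys, ifelse(mask, 1, 0), threshold = 0.5,
                      keypoint_id = kp)
}

# a minimal preprocessed-trial stand-in for ag_raw(): exact trajectories
make_prep <- function(neck, hip, wrist, elbow, ankle, knee,
                      side = "left_extended") {
  as_traj <- function(m) {
    m <- if (is.matrix(m)) m else matrix(m, ncol = 2, byrow = TRUE)
    structure(list(x = m[, 1], y = m[, 2], mask = rep(TRUE, nrow(m)),
                   keypoint_id = "fixture"), class = "trajectory")
  }
  ext <- extended_keypoints(side)
  traj <- list(as_traj(neck), as_traj(hip), as_traj(wrist), as_traj(elbow),
               as_traj(ankle), as_traj(knee))
  names(traj) <- c("Neck", "MidHip", ext$wrist, ext$elbow, ext$ankle, ext$knee)
  list(traj = traj, n = length(traj[[1]]$x), side = side)
}

# Eq-style naive oracles -----------------------------------------------------

naive_moving_distance <- function(xy, bl) {
  n <- nrow(xy)
  total <- 0
  for (i in 2:n) {
    total <- total + sqrt((xy[i, 1] - xy[i - 1, 1])^2 +
                            (xy[i, 2] - xy[i - 1, 2])^2) / bl
  }
  total / (n - 1)
}

naive_ag_raw <- function(prep) {
  ext <- extended_keypoints(prep$side)
  tr <- prep$traj
  total <- 0
  n <- length(tr$Neck$x)
  for (i in seq_len(n)) {
    ang <- function(ox, oy, tx, ty) {
      dx <- abs(tx - ox); dy <- abs(ty - oy)
      if (dx == 0) 90 else atan(dy / dx) * 180 / pi
    }
    phi <- ang(tr$Neck$x[i], tr$Neck$y[i],
               (tr[[ext$wrist]]$x[i] + tr[[ext$elbow]]$x[i]) / 2,
               (tr[[ext$wrist]]$y[i] + tr[[ext$elbow]]$y[i]) / 2)
    theta <- ang(tr$MidHip$x[i], tr$MidHip$y[i],
                 (tr[[ext$ankle]]$x[i] + tr[[ext$knee]]$x[i]) / 2,
                 (tr[[ext$ankle]]$y[i] + tr[[ext$knee]]$y[i]) / 2)
    total <- total + abs(phi) + abs(theta)
  }
  -total / n
}

# average ranks by counting, independent of base rank()
brute_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (1 + sum(v == v[i])) / 2
  }, numeric(1))
}

# ICC(2,1) via stats::aov mean squares (long-format two-way ANOVA)
aov_icc_2_1 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  long <- data.frame(score = as.vector(x),
                     target = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(score ~ target + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# random in-bounds keypoint frame for rotation properties
random_frame <- function(width = 1280, height = 720) {
  make_frame(x = runif(25, 0, width - 1), y = runif(25, 0, height - 1),
             conf = runif(25))
}
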