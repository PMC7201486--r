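# Confidence masking, gap interpolation, and the body-length normalizer.

#' Mask low-confidence detections in a keypoint trajectory
#'
#' Frames whose detection confidence is strictly below the threshold are
#' marked invalid; a confidence of exactly the threshold is kept. The
#' undetected sentinel (confidence 0) is masked by the same rule.
#'
#' @param xs,ys per-frame pixel coordinates.
#' @param confidences per-frame detection confidences in `[0, 1]`.
#' @param threshold strict lower bound for keeping a frame (default 0.5).
#' @param keypoint_id label used in downstream error messages.
#' @return a `trajectory` object: list with `x`, `y`, `mask` (TRUE = valid)
#'   and `keypoint_id`.
#' @export
mask_low_confidence <- function(xs, ys, confidences, threshold = 0.5,
                                keypoint_id = NA_character_) {
  stopifnot(length(xs) == length(ys), length(xs) == length(confidences))
  structure(
    list(x = as.numeric(xs), y = as.numeric(ys),
         mask = confidences >= threshold, keypoint_id = keypoint_id),
    class = "trajectory"
  )
}

#' Fill masked gaps in a trajectory by linear interpolation
#'
#' Interior gaps are filled linearly against frame index, per coordinate.
#' Leading and trailing gaps cannot be interpolated and are filled with the
#' nearest valid value (constant extension). Valid samples are never
#' modified; the output mask is all TRUE. Idempotent.
#'
#' @param traj a `trajectory` from [mask_low_confidence()].
#' @return the gap-filled `trajectory`.
#' @export
interpolate_gaps <- function(traj) {
  mask <- traj$mask
  n <- length(mask)
  if (!any(mask)) {
    bd_stop("all_masked_error",
            "keypoint %s: all %d frames below the confidence threshold",
            traj$keypoint_id, n)
  }
  if (all(mask)) return(traj)
  idx <- seq_len(n)
  fill <- function(v) {
    out <- v
    if (sum(mask) == 1L) {
      out[!mask] <- v[mask]    # rule = 2 needs >= 2 points
    } else {
      out[!mask] <- stats::approx(idx[mask], v[mask], xout = idx[!mask],
                                  method = "linear", rule = 2)$y
    }
    out
  }
  traj$x <- fill(traj$x)
  traj$y <- fill(traj$y)
  traj$mask <- rep(TRUE, n)
  traj
}

traj_xy <- function(traj) cbind(x = traj$x, y = traj$y)

#' Body length: the mean neck-to-hip keypoint distance
#'
#' The per-trial scale normalizer: the Euclidean distance between the neck
#' (BODY_25 index 1) and mid-hip (index 8) keypoints, averaged over all
#' frames. Dividing displacements by it removes camera-distance and
#' body-size effects.
#'
#' @param neck_traj,hip_traj interpolated `trajectory` objects of equal
#'   length.
#' @param tol degenerate-body guard: mean distance at or below this many
#'   pixels is rejected.
#' @return body length in pixels (> 0).
#' @export
body_length <- function(neck_traj, hip_traj, tol = 1e-6) {
  stopifnot(length(neck_traj$x) == length(hip_traj$x))
  d <- sqrt((neck_traj$x - hip_traj$x)^2 + (neck_traj$y - hip_traj$y)^2)
  bl <- mean(d)
  if (!is.finite(bl) || bl <= tol) {
    bd_stop("degenerate_body_error",
            "mean neck-hip distance %.3g px is degenerate", bl)
  }
  bl
}

#' Extract, mask and interpolate the trajectories a trial needs
#'
#' Runs the per-keypoint preprocessing (confidence masking then gap filling)
#' on the requested keypoints of a recording and computes the body length.
#'
#' @param recording a [trial_recording()].
#' @param keypoints BODY_25 keypoint names to preprocess; defaults to the
#'   neck, mid-hip, and the extended and supporting limb keypoints for the
#'   recording's side.
#' @param threshold confidence threshold (strict `<` masks).
#' @param frame_range optional integer `c(first, last)` 1-based frame window
#'   to restrict to before preprocessing.
#' @return list with `traj` (named list of interpolated `trajectory`
#'   objects), `bl` (body length, px), `n` (frames) and `side`.
#' @export
preprocess_trial <- function(recording, keypoints = NULL, threshold = 0.5,
                             frame_range = NULL) {
  ext <- extended_keypoints(recording$side)
  if (is.null(keypoints)) {
    keypoints <- unique(c("Neck", "MidHip", unlist(ext, use.names = FALSE)))
  }
  arr <- recording$frames
  if (!is.null(frame_range)) {
    arr <- arr[frame_range[1]:frame_range[2], , , drop = FALSE]
  }
  trajs <- lapply(keypoints, function(kp) {
    tr <- mask_low_confidence(arr[, kp, "x"], arr[, kp, "y"],
                              arr[, kp, "confidence"],
                              threshold = threshold, keypoint_id = kp)
    tryCatch(interpolate_gaps(tr), all_masked_error = function(e) {
      bd_stop("all_masked_error", "trial %s: %s",
              recording$participant_id, conditionMessage(e))
    })
  })
  names(trajs) <- keypoints
  list(traj = trajs,
       bl = body_length(trajs[["Neck"]], trajs[["MidHip"]]),
       n = dim(arr)[1],
       side = recording$side)
}
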