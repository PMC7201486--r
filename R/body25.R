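#' BODY_25 keypoint names
#'
#' Landmark names in the BODY_25 convention, in output order (0-based indices
#' 0..24). Index 1 is the neck, index 8 the mid-hip; 15-24 are face and foot
#' points that are parsed but unused by the indices.
#'
#' @return character vector of length 25.
#' @export
#' @examples
#' body25_keypoints()[7] # left elbow (0-based index 6)
body25_keypoints <- function() {
  c("Nose", "Neck", "RShoulder", "RElbow", "RWrist",
    "LShoulder", "LElbow", "LWrist", "MidHip",
    "RHip", "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
    "REye", "LEye", "REar", "LEar",
    "LBigToe", "LSmallToe", "LHeel", "RBigToe", "RSmallToe", "RHeel")
}

#' Row index of a named BODY_25 keypoint
#'
#' @param name keypoint name, e.g. `"LElbow"`.
#' @return 1-based row index into a keypoint frame matrix.
#' @export
body25_index <- function(name) {
  i <- match(name, body25_keypoints())
  if (anyNA(i)) {
    bd_stop("format_error", "unknown BODY_25 keypoint name: %s",
            paste(name[is.na(i)], collapse = ", "))
  }
  i
}

task_sides <- c("left_extended", "right_extended")

#' Keypoints of the extended and supporting limbs for a trial side
#'
#' In the bird-dog posture one arm is lifted together with the contralateral
#' leg: `left_extended` means the left arm and the right leg are extended,
#' and vice versa.
#'
#' @param side `"left_extended"` or `"right_extended"`.
#' @return named list of BODY_25 keypoint names: `wrist`, `elbow` (extended
#'   arm), `knee`, `ankle` (extended leg), and `support_wrist`,
#'   `support_knee`, `support_ankle` on the floor-contact side.
#' @export
extended_keypoints <- function(side) {
  side <- match.arg(side, task_sides)
  if (side == "left_extended") {
    list(wrist = "LWrist", elbow = "LElbow", knee = "RKnee", ankle = "RAnkle",
         support_wrist = "RWrist", support_knee = "LKnee",
         support_ankle = "LAnkle")
  } else {
    list(wrist = "RWrist", elbow = "RElbow", knee = "LKnee", ankle = "LAnkle",
         support_wrist = "LWrist", support_knee = "RKnee",
         support_ankle = "RAnkle")
  }
}
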