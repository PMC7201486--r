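# Reading and writing the OpenPose BODY_25 per-frame JSON dialect, the
# 90-degree rotation convention, and the derived indices table.

#' Parse one OpenPose-dialect JSON frame
#'
#' Each frame file holds an object with a `people` list; every person carries
#' a flat `pose_keypoints_2d` vector of 75 numbers
#' `[x0, y0, c0, ..., x24, y24, c24]` in BODY_25 order. When several people
#' are detected the one with the highest summed confidence is kept (the task
#' records a single child, but plumbing must be deterministic).
#'
#' @param json_text the JSON text of one frame file.
#' @param frame_index 0-based frame ordinal, used in error messages and
#'   attached to the result.
#' @return a 25 x 3 numeric matrix (columns `x`, `y`, `confidence`, rows
#'   named by [body25_keypoints()]) with attribute `frame_index`. An
#'   undetected keypoint is the sentinel row `(0, 0, 0)`.
#' @export
#' @examples
#' kp <- matrix(c(1, 2, 0.9), 25, 3, byrow = TRUE)
#' txt <- jsonlite::toJSON(list(people = list(list(
#'   pose_keypoints_2d = as.vector(t(kp))))), auto_unbox = TRUE)
#' parse_openpose_frame(txt, 0)["Neck", ]
parse_openpose_frame <- function(json_text, frame_index = 0L) {
  obj <- tryCatch(
    jsonlite::fromJSON(json_text, simplifyVector = FALSE),
    error = function(e) {
      bd_stop("format_error", "frame %d: invalid JSON (%s)",
              frame_index, conditionMessage(e))
    }
  )
  people <- obj$people
  if (is.null(people) || length(people) == 0L) {
    bd_stop("missing_person_error", "frame %d: no person detected", frame_index)
  }
  mats <- lapply(seq_along(people), function(i) {
    flat <- unlist(people[[i]]$pose_keypoints_2d, use.names = FALSE)
    if (length(flat) != 75L || !is.numeric(flat)) {
      bd_stop("format_error",
              "frame %d, person %d: pose_keypoints_2d has length %d, expected 75",
              frame_index, i, length(flat))
    }
    matrix(flat, ncol = 3L, byrow = TRUE,
           dimnames = list(body25_keypoints(), c("x", "y", "confidence")))
  })
  conf_sums <- vapply(mats, function(m) sum(m[, "confidence"]), numeric(1))
  out <- mats[[which.max(conf_sums)]]
  attr(out, "frame_index") <- as.integer(frame_index)
  out
}

undetected_frame <- function(frame_index) {
  out <- matrix(0, 25L, 3L,
                dimnames = list(body25_keypoints(), c("x", "y", "confidence")))
  attr(out, "frame_index") <- as.integer(frame_index)
  out
}

#' Construct a trial recording
#'
#' The canonical internal orientation is the original video orientation
#' (participant horizontal, image origin top-left, y increasing downward);
#' all index math operates there.
#'
#' @param frames either a list of 25 x 3 keypoint matrices (see
#'   [parse_openpose_frame()]) or an `n x 25 x 3` array.
#' @param side which arm is lifted: `"left_extended"` or `"right_extended"`
#'   (the lifted leg is contralateral).
#' @param fps frame rate in frames/second, > 0.
#' @param participant_id opaque participant label.
#' @param image_width,image_height pixel dimensions of the video frame.
#' @param annotated_start_frame 0-based ordinal of posture onset (default 0).
#' @param annotated_fall_frame optional 0-based ordinal of first floor
#'   contact of an extended limb; `NULL` when no fall occurred.
#' @return an object of class `trial_recording`: a list with the above
#'   metadata and `frames`, an `n x 25 x 3` array.
#' @export
trial_recording <- function(frames, side, fps, participant_id = "trial",
                            image_width = 1280L, image_height = 720L,
                            annotated_start_frame = 0L,
                            annotated_fall_frame = NULL) {
  side <- match.arg(side, task_sides)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    bd_stop("metadata_error", "fps must be a single positive number, got %s",
            deparse(fps))
  }
  if (is.list(frames)) {
    n <- length(frames)
    arr <- array(NA_real_, c(n, 25L, 3L),
                 dimnames = list(NULL, body25_keypoints(),
                                 c("x", "y", "confidence")))
    for (i in seq_len(n)) arr[i, , ] <- frames[[i]]
  } else {
    arr <- frames
    n <- dim(arr)[1]
    dimnames(arr) <- list(NULL, body25_keypoints(), c("x", "y", "confidence"))
  }
  if (n < 2L) {
    bd_stop("too_short_error",
            "trial %s: needs at least 2 frames, got %d", participant_id, n)
  }
  structure(
    list(participant_id = participant_id, side = side, fps = fps,
         frames = arr, image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         annotated_start_frame = as.integer(annotated_start_frame),
         annotated_fall_frame = if (!is.null(annotated_fall_frame))
           as.integer(annotated_fall_frame)),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  n <- dim(x$frames)[1]
  cat(sprintf("<trial_recording> %s, %s, %d frames @ %g fps (%.1f s)\n",
              x$participant_id, x$side, n, x$fps, n / x$fps))
  if (!is.null(x$annotated_fall_frame)) {
    cat(sprintf("  annotated fall at frame %d (%.1f s)\n",
                x$annotated_fall_frame, x$annotated_fall_frame / x$fps))
  }
  invisible(x)
}

#' Number of frames in a recording
#' @param recording a [trial_recording()].
#' @return integer frame count.
#' @export
n_frames <- function(recording) dim(recording$frames)[1]

#' Load a trial directory of OpenPose JSON frames
#'
#' Files matching `*_keypoints.json` are read in sorted order (OpenPose names
#' them with a zero-padded frame number, so lexicographic order is frame
#' order; on-disk enumeration order is irrelevant). Frames where no person
#' was detected are retained as fully undetected frames (all confidences 0)
#' so downstream masking and interpolation treat them as gaps.
#'
#' @param directory path holding one JSON file per frame.
#' @inheritParams trial_recording
#' @return a [trial_recording()].
#' @export
load_trial <- function(directory, side, fps, participant_id = basename(directory),
                       image_width = 1280L, image_height = 720L,
                       annotated_start_frame = 0L, annotated_fall_frame = NULL) {
  files <- sort(list.files(directory, pattern = "_keypoints\\.json$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    bd_stop("empty_trial_error", "no *_keypoints.json files in %s", directory)
  }
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    txt <- paste(readLines(files[i], warn = FALSE), collapse = "\n")
    frames[[i]] <- tryCatch(
      parse_openpose_frame(txt, frame_index = i - 1L),
      missing_person_error = function(e) undetected_frame(i - 1L),
      format_error = function(e) {
        bd_stop("format_error", "%s: %s", files[i], conditionMessage(e))
      }
    )
  }
  trial_recording(frames, side = side, fps = fps,
                  participant_id = participant_id,
                  image_width = image_width, image_height = image_height,
                  annotated_start_frame = annotated_start_frame,
                  annotated_fall_frame = annotated_fall_frame)
}

#' Rotate a keypoint frame by 90 degrees
#'
#' Pose estimators detect horizontal (quadrupedal) participants poorly, so
#' the video is rotated 90 degrees head-up before detection and the detected
#' keypoints are rotated 90 degrees back. `cw90` maps
#' `(x, y) -> (H - 1 - y, x)` and `ccw90` maps `(x, y) -> (y, W - 1 - x)`,
#' where `W x H` are the dimensions of the image the coordinates currently
#' live in; the two are mutual inverses. Undetected `(0, 0, 0)` sentinel rows
#' pass through unchanged, as do confidences.
#'
#' @param frame 25 x 3 keypoint matrix.
#' @param direction `"cw90"` or `"ccw90"`.
#' @param image_width,image_height dimensions (pixels) of the current image.
#' @return the rotated 25 x 3 matrix.
#' @export
rotate_frame <- function(frame, direction = c("cw90", "ccw90"),
                         image_width, image_height) {
  direction <- match.arg(direction)
  out <- frame
  sentinel <- frame[, 1] == 0 & frame[, 2] == 0 & frame[, 3] == 0
  live <- !sentinel
  oob <- live & (frame[, 1] < 0 | frame[, 1] >= image_width |
                   frame[, 2] < 0 | frame[, 2] >= image_height)
  if (any(oob)) {
    warning(sprintf("rotate_frame: %d keypoint(s) outside [0,%d)x[0,%d); passed through",
                    sum(oob), image_width, image_height))
  }
  if (direction == "cw90") {
    out[live, 1] <- image_height - 1 - frame[live, 2]
    out[live, 2] <- frame[live, 1]
  } else {
    out[live, 1] <- frame[live, 2]
    out[live, 2] <- image_width - 1 - frame[live, 1]
  }
  out
}

indices_columns <- c("participant_id", "side", "DT_s", "D_prime", "a_raw",
                     "SPB", "AG")

#' Write / read the per-trial indices table
#'
#' Plain UTF-8 CSV with '.' decimal and at least the columns
#' `participant_id, side, DT_s, D_prime, a_raw, SPB, AG`; any extra columns
#' (e.g. the four per-keypoint moving distances) are preserved. The
#' round trip is lossless to printed precision (15 significant digits).
#'
#' @param rows data frame of per-trial indices (e.g. from [score_cohort()]).
#' @param path file path.
#' @return `write_indices_table()` returns `path` invisibly;
#'   `read_indices_table()` returns the data frame.
#' @export
write_indices_table <- function(rows, path) {
  missing_cols <- setdiff(indices_columns, names(rows))
  if (length(missing_cols)) {
    bd_stop("format_error", "indices table lacks column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_indices_table
#' @export
read_indices_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(indices_columns, names(df))
  if (length(missing_cols)) {
    bd_stop("format_error", "%s: malformed header, missing column(s): %s",
            path, paste(missing_cols, collapse = ", "))
  }
  num_cols <- setdiff(indices_columns, c("participant_id", "side"))
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & nzchar(df[[cn]])) # non-numeric text
    bad <- c(bad, which(is.na(df[[cn]])))
    if (length(bad)) {
      bd_stop("format_error", "%s: non-numeric %s value in row %d",
              path, cn, min(bad))
    }
    df[[cn]] <- v
  }
  df
}

#' Write a recording as an OpenPose-dialect JSON directory
#'
#' Emits one `<trial_id>_<%012d>_keypoints.json` per frame, matching the
#' layout [load_trial()] reads.
#'
#' @param recording a [trial_recording()].
#' @param directory output directory (created if needed).
#' @param trial_id file-name stem; defaults to the participant id.
#' @return the directory, invisibly.
#' @export
write_openpose_trial <- function(recording, directory,
                                 trial_id = recording$participant_id) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(recording)
  for (i in seq_len(n)) {
    flat <- as.vector(t(recording$frames[i, , ]))
    obj <- list(version = 1.3,
                people = list(list(pose_keypoints_2d = flat)))
    path <- file.path(directory,
                      sprintf("%s_%012d_keypoints.json", trial_id, i - 1L))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  }
  invisible(directory)
}
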