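#' Construct a skeleton recording
#'
#' A recording is a T x 25 x 3 array of joint positions in meters at a fixed
#' frame rate. Axis convention follows the sensor: X grows to the sensor's
#' left, Y up, Z out from the sensor toward the walker.
#'
#' @param positions Numeric array T x 25 x 3 (frames x joints x axes X,Y,Z).
#' @param frame_rate Sampling rate in Hz (default 30).
#' @param participant_id Identifier string.
#' @param group_label Optional binary label (1 = case, 0 = control) or NA.
#' @param coordinate_frame "sensor" or "spine_relative".
#' @param sensor_spine Optional T x 3 matrix: the sensor-frame spine
#'   trajectory retained alongside a spine-relative recording (needed for
#'   walking speed).
#' @return Object of class `skeleton_recording`.
#' @export
skeleton_recording <- function(positions, frame_rate = 30,
                               participant_id = "anon",
                               group_label = NA,
                               coordinate_frame = c("sensor", "spine_relative"),
                               sensor_spine = NULL) {
  coordinate_frame <- match.arg(coordinate_frame)
  if (length(dim(positions)) != 3L || dim(positions)[2] != 25L ||
      dim(positions)[3] != 3L) {
    stop("positions must be a T x 25 x 3 array", call. = FALSE)
  }
  if (dim(positions)[1] < 2L) stop("recording needs T >= 2 frames", call. = FALSE)
  dimnames(positions) <- list(NULL, as.character(1:25), c("x", "y", "z"))
  rec <- list(
    positions = positions,
    frame_rate = frame_rate,
    participant_id = as.character(participant_id),
    group_label = group_label,
    coordinate_frame = coordinate_frame,
    joint_map_version = JOINT_MAP_VERSION,
    sensor_spine = sensor_spine
  )
  class(rec) <- "skeleton_recording"
  rec
}

#' @export
print.skeleton_recording <- function(x, ...) {
  cat(sprintf(
    "<skeleton_recording> %s: %d frames @ %g Hz, %s frame, group=%s\n",
    x$participant_id, nrow(x$positions), x$frame_rate,
    x$coordinate_frame, format(x$group_label)
  ))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec A `skeleton_recording`.
#' @return Integer frame count.
#' @export
n_frames <- function(rec) dim(rec$positions)[1]

#' Validate a skeleton recording
#'
#' Checks every invariant a downstream stage relies on and reports (rather
#' than raises) the violations: at least 2 frames, positive frame rate, and
#' no non-finite coordinates. Issues carry the frame/joint/axis address of
#' the offending value.
#'
#' @param rec A `skeleton_recording`.
#' @return A data.frame with columns `frame`, `joint`, `axis`, `message`;
#'   zero rows iff the recording is clean. Recording-level issues (e.g. a
#'   nonpositive frame rate) have NA coordinates.
#' @export
validate_recording <- function(rec) {
  issues <- data.frame(frame = integer(), joint = integer(),
                       axis = character(), message = character(),
                       stringsAsFactors = FALSE)
  add <- function(frame, joint, axis, message) {
    rbind(issues, data.frame(frame = frame, joint = joint, axis = axis,
                             message = message, stringsAsFactors = FALSE))
  }
  if (!inherits(rec, "skeleton_recording")) {
    return(add(NA_integer_, NA_integer_, NA_character_,
               "not a skeleton_recording"))
  }
  if (!is.numeric(rec$frame_rate) || length(rec$frame_rate) != 1 ||
      !is.finite(rec$frame_rate) || rec$frame_rate <= 0) {
    issues <- add(NA_integer_, NA_integer_, NA_character_,
                  "nonpositive frame rate")
  }
  if (n_frames(rec) < 2L) {
    issues <- add(NA_integer_, NA_integer_, NA_character_,
                  "fewer than 2 frames")
  }
  bad <- which(!is.finite(rec$positions), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    axes <- c("x", "y", "z")
    for (r in seq_len(nrow(bad))) {
      issues <- add(bad[r, 1], bad[r, 2], axes[bad[r, 3]],
                    "non-finite coordinate")
    }
  }
  issues
}
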