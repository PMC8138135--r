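#' Five-point binomial Gaussian kernel
#'
#' The low-pass kernel used throughout: (1/16) * [1, 4, 6, 4, 1]. It sums to
#' one, so constant signals (and boundary frames, under edge replication)
#' pass through unchanged.
#'
#' @return Numeric vector of 5 coefficients.
#' @export
gaussian_kernel <- function() c(1, 4, 6, 4, 1) / 16

#' Gaussian low-pass filter a signal
#'
#' Discrete convolution of each channel with [gaussian_kernel()]. Output
#' length equals input length; boundaries are handled by edge replication
#' (configurable to zero padding).
#'
#' @param x Numeric vector, or a matrix whose columns are filtered
#'   independently.
#' @param boundary "replicate" (default) or "zero".
#' @return Filtered vector/matrix of the same shape.
#' @export
gaussian_filter <- function(x, boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  if (is.matrix(x)) return(apply(x, 2, gaussian_filter, boundary = boundary))
  n <- length(x)
  if (n < 5) stop("series too short to filter (need length >= 5)", call. = FALSE)
  pad <- if (boundary == "replicate") {
    c(rep(x[1], 2), x, rep(x[n], 2))
  } else {
    c(0, 0, x, 0, 0)
  }
  k <- gaussian_kernel()
  y <- stats::filter(pad, k, method = "convolution", sides = 2)
  as.numeric(y[3:(n + 2)])
}

filter_positions <- function(positions, boundary = "replicate") {
  tt <- dim(positions)[1]
  flat <- matrix(positions, nrow = tt)
  out <- apply(flat, 2, gaussian_filter, boundary = boundary)
  array(out, dim = dim(positions), dimnames = dimnames(positions))
}

#' Transform a recording to spine-relative coordinates
#'
#' Subtracts the same-frame spine (joint 9) position from every joint,
#' removing whole-body translation; the sensor-frame spine trajectory is
#' retained on the result because walking speed is only measurable in the
#' sensor frame.
#'
#' @param rec A sensor-frame [skeleton_recording()].
#' @return A spine-relative recording with `$sensor_spine` set.
#' @export
to_spine_relative <- function(rec) {
  if (rec$coordinate_frame == "spine_relative") {
    stop("recording is already spine-relative", call. = FALSE)
  }
  spine <- rec$positions[, 9, , drop = TRUE]
  if (is.null(dim(spine))) spine <- matrix(spine, ncol = 3)
  pos <- rec$positions
  for (a in 1:3) pos[, , a] <- pos[, , a] - spine[, a]
  skeleton_recording(pos, frame_rate = rec$frame_rate,
                     participant_id = rec$participant_id,
                     group_label = rec$group_label,
                     coordinate_frame = "spine_relative",
                     sensor_spine = spine)
}

#' Split a recording into face-toward and back-toward walking passes
#'
#' Walking toward the sensor strictly decreases the spine Z coordinate under
#' the sensor axis convention, so passes are maximal runs of the sign of the
#' smoothed spine-Z velocity: negative = toward, positive = away. Runs
#' shorter than `min_pass_s` (direction flicker at turns) are merged into
#' the preceding run.
#'
#' @param rec A sensor-frame recording, or a spine-relative one carrying
#'   `$sensor_spine`.
#' @param min_pass_s Minimum pass duration in seconds (default 1).
#' @return data.frame with 0-based inclusive-exclusive `start`, `end` and
#'   `direction` ("toward"/"away"); passes are disjoint and ordered.
#' @export
split_walk_passes <- function(rec, min_pass_s = 1) {
  z <- sensor_spine_z(rec)
  fps <- rec$frame_rate
  w <- max(5, round(fps / 2))
  zs <- stats::filter(c(rep(z[1], w), z, rep(z[length(z)], w)),
                      rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
  zs <- as.numeric(zs[(w + 1):(w + length(z))])
  v <- diff(zs)
  dir <- ifelse(v < 0, -1L, 1L)
  runs <- rle(dir)
  # merge runs shorter than the minimum into their left neighbor
  min_len <- max(1, round(min_pass_s * fps))
  repeat {
    short <- which(runs$lengths < min_len)
    if (length(short) == 0 || length(runs$lengths) == 1) break
    i <- short[1]
    j <- if (i == 1) 2 else i - 1
    runs$lengths[j] <- runs$lengths[j] + runs$lengths[i]
    runs$lengths <- runs$lengths[-i]
    runs$values <- runs$values[-i]
    runs <- rle(inverse.rle(runs))
  }
  ends <- cumsum(runs$lengths)
  starts <- c(0L, ends[-length(ends)])
  passes <- data.frame(
    start = starts,
    end = ends + 1L,  # velocity index i covers frames i..i+1
    direction = ifelse(runs$values < 0, "toward", "away"),
    stringsAsFactors = FALSE
  )
  passes$end <- pmin(passes$end, length(z))
  passes <- passes[passes$end > passes$start, , drop = FALSE]
  # make passes disjoint: end of pass i = start of pass i+1
  if (nrow(passes) > 1) passes$end[-nrow(passes)] <- passes$start[-1]
  if (!any(passes$direction == "toward")) {
    stop("segmentation error: no face-toward pass found", call. = FALSE)
  }
  rownames(passes) <- NULL
  passes
}

sensor_spine_z <- function(rec) {
  if (rec$coordinate_frame == "sensor") return(rec$positions[, 9, 3])
  if (!is.null(rec$sensor_spine)) return(rec$sensor_spine[, 3])
  stop("spine-relative recording lacks the retained sensor spine track",
       call. = FALSE)
}

#' Select the middle face-toward pass
#'
#' Of k face-toward passes, returns the ceiling(k/2)-th (for an even k the
#' tie is broken toward the earlier pass), avoiding the unnatural movements
#' at the start and end of the protocol.
#'
#' @param passes data.frame from [split_walk_passes()].
#' @return One-row data.frame (`start`, `end`, `direction`).
#' @export
select_middle_face_toward <- function(passes) {
  toward <- passes[passes$direction == "toward", , drop = FALSE]
  if (nrow(toward) == 0) {
    stop("segmentation error: no face-toward pass found", call. = FALSE)
  }
  toward[ceiling(nrow(toward) / 2), , drop = FALSE]
}

#' Detect toe-off events in a left-toe vertical trajectory
#'
#' A toe-off is operationalized as a local minimum of the (already
#' Gaussian-filtered) left-toe Y series followed by a sustained rise: within
#' the next `refractory_s` seconds the signal must climb by at least
#' `rise_frac` of the series range. Since the toe leaves the ground from its lowest point, a
#' candidate must also lie in the bottom `depth_frac` of the series range,
#' which rejects residual-noise dimples on the swing flanks. Events closer
#' than `refractory_s` to the previous kept event are discarded.
#'
#' @param left_toe_y Filtered numeric series (spine-relative left-toe Y).
#' @param frame_rate Hz.
#' @param refractory_s Minimum spacing between events in seconds (default 0.5).
#' @param rise_frac Required rise as a fraction of the series range
#'   (default 0.12).
#' @param depth_frac Candidates must satisfy y <= min + depth_frac * range
#'   (default 0.3).
#' @return Integer vector of 1-based frame indices.
#' @export
detect_toe_off_events <- function(left_toe_y, frame_rate,
                                  refractory_s = 0.5, rise_frac = 0.12,
                                  depth_frac = 0.3) {
  n <- length(left_toe_y)
  rng <- max(left_toe_y) - min(left_toe_y)
  if (!is.finite(rng) || rng < 1e-9) {
    stop("segmentation error: insufficient gait cycles (flat trajectory)",
         call. = FALSE)
  }
  y <- left_toe_y
  cand <- which(diff(sign(diff(y))) > 0) + 1L  # strict local minima
  cand <- cand[y[cand] <= min(y) + depth_frac * rng]
  look <- max(2L, round(refractory_s * frame_rate))
  keep <- vapply(cand, function(i) {
    j <- min(n, i + look)
    max(y[i:j]) - y[i] >= rise_frac * rng
  }, logical(1))
  cand <- cand[keep]
  refr <- refractory_s * frame_rate
  events <- integer(0)
  for (i in cand) {
    if (length(events) == 0 || i - events[length(events)] >= refr) {
      events <- c(events, i)
    }
  }
  events
}

#' Extract the two-cycle gait segment from a recording
#'
#' Runs toe-off detection on the Gaussian-filtered spine-relative left-toe Y
#' within the given frame interval, centers on the middle toe-off events,
#' and returns the frames spanning two gait cycles. The stored relative
#' positions are filtered once, after cropping; the sensor-frame spine Z is
#' carried unfiltered for walking speed.
#'
#' @param rec Spine-relative recording with `$sensor_spine`.
#' @param interval One-row pass data.frame (0-based `start`, `end`) or a
#'   length-2 vector; defaults to the whole recording.
#' @param events Optional precomputed toe-off indices (1-based, absolute).
#' @param boundary Filter boundary policy, see [gaussian_filter()].
#' @return A `gait_segment`: list with `relative_positions` (T' x 25 x 3,
#'   filtered), `sensor_spine_z` (T', unfiltered), `frame_rate`,
#'   `cycle_boundaries` (0, b, T'), `duration_s`.
#' @export
extract_two_cycle_segment <- function(rec, interval = NULL, events = NULL,
                                      boundary = "replicate") {
  if (rec$coordinate_frame != "spine_relative") {
    stop("segment extraction expects a spine-relative recording", call. = FALSE)
  }
  tt <- n_frames(rec)
  if (is.null(interval)) {
    lo <- 1L; hi <- tt
  } else if (is.data.frame(interval)) {
    lo <- interval$start[1] + 1L; hi <- interval$end[1]
  } else {
    lo <- interval[1] + 1L; hi <- interval[2]
  }
  if (is.null(events)) {
    toe_y <- gaussian_filter(rec$positions[lo:hi, 24, 2], boundary = boundary)
    events <- detect_toe_off_events(toe_y, rec$frame_rate) + lo - 1L
  } else {
    events <- events[events >= lo & events < hi]
  }
  k <- length(events)
  if (k < 3) {
    stop("segmentation error: insufficient gait cycles (need >= 3 toe-offs, got ",
         k, ")", call. = FALSE)
  }
  j <- ceiling((k - 2) / 2)  # central window of three consecutive events
  e <- events[j:(j + 2)]
  idx <- e[1]:(e[3] - 1L)
  seg <- list(
    relative_positions = filter_positions(
      rec$positions[idx, , , drop = FALSE], boundary = boundary),
    sensor_spine_z = sensor_spine_z(rec)[idx],
    frame_rate = rec$frame_rate,
    cycle_boundaries = c(0L, e[2] - e[1], e[3] - e[1]),
    duration_s = length(idx) / rec$frame_rate,
    participant_id = rec$participant_id,
    group_label = rec$group_label
  )
  class(seg) <- "gait_segment"
  seg
}

#' @export
print.gait_segment <- function(x, ...) {
  cat(sprintf(
    "<gait_segment> %s: %d frames (%.2f s), cycle boundaries %s\n",
    x$participant_id, length(x$sensor_spine_z), x$duration_s,
    paste(x$cycle_boundaries, collapse = "/")
  ))
  invisible(x)
}

#' Full preprocessing chain for one recording
#'
#' Sensor-frame recording in, two-cycle gait segment out: spine-relative
#' transform, pass splitting on the sensor spine Z, middle face-toward pass
#' selection, toe-off detection on the filtered left-toe Y, and two-cycle
#' cropping with post-crop filtering.
#'
#' If the middle face-toward pass holds fewer than three toe-off events
#' (a fast walker on a short path), the other face-toward passes are tried
#' in order of distance from the middle (earlier first on ties); the
#' segmentation error propagates only if every pass fails.
#'
#' @param rec A sensor-frame [skeleton_recording()].
#' @param min_pass_s Passed to [split_walk_passes()].
#' @param boundary Filter boundary policy.
#' @return A `gait_segment`.
#' @export
preprocess_recording <- function(rec, min_pass_s = 1, boundary = "replicate") {
  rel <- to_spine_relative(rec)
  passes <- split_walk_passes(rel, min_pass_s = min_pass_s)
  toward <- passes[passes$direction == "toward", , drop = FALSE]
  mid_i <- ceiling(nrow(toward) / 2)
  order_try <- order(abs(seq_len(nrow(toward)) - mid_i),
                     seq_len(nrow(toward)))
  err <- NULL
  for (i in order_try) {
    seg <- tryCatch(
      extract_two_cycle_segment(rel, interval = toward[i, , drop = FALSE],
                                boundary = boundary),
      error = function(e) e)
    if (!inherits(seg, "error")) return(seg)
    err <- seg
  }
  stop(err)
}
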