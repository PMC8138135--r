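#' Sample moment statistics of a series
#'
#' Mean, sample SD (n-1 denominator), skewness g1 = m3 / m2^(3/2) and excess
#' kurtosis g2 = m4 / m2^2 - 3, with central moments m_k computed with a 1/n
#' denominator. A zero-variance series has skewness and kurtosis defined as
#' 0 so that degenerate channels stay finite.
#'
#' @param x Numeric vector of length >= 4.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
moment_stats <- function(x) {
  n <- length(x)
  if (n < 4) stop("moment_stats needs length >= 4", call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  s <- stats::sd(x)
  scale2 <- mean(x^2) + 1
  if (m2 < 1e-14 * scale2) {
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0))
  }
  c(mean = m, sd = s,
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

#' Discrete Fourier transform of a series
#'
#' F_k = sum_j x_j exp(-2 pi i k j / n), k = 0..n-1. Returns the DC
#' component F_0 / n (the signal mean), and the amplitudes |F_k| and
#' principal-value phases arg(F_k) in (-pi, pi] for k = 1..n-1 (the full
#' spectrum excluding DC).
#'
#' @param x Numeric vector, length >= 2.
#' @return List with `dc`, `amplitudes`, `phases`.
#' @export
dft <- function(x) {
  n <- length(x)
  if (n < 2) stop("dft needs length >= 2", call. = FALSE)
  f <- stats::fft(x)
  list(dc = Re(f[1]) / n,
       amplitudes = Mod(f[-1]),
       phases = Arg(f[-1]))
}

seg_channel <- function(segment, joint, axis) {
  a <- match(axis, c("x", "y", "z"))
  segment$relative_positions[, joint, a]
}

cycle_frames <- function(segment, cycle) {
  b <- segment$cycle_boundaries
  (b[cycle] + 1):b[cycle + 1]
}

#' Spatiotemporal gait features (10)
#'
#' Stride-level descriptors computed per gait cycle and averaged over the
#' segment's two cycles:
#' \describe{
#'   \item{body_sway}{max over frames of |x_shoulderL - x_shoulderR|}
#'   \item{arm_swing_left/right}{max - min of the relative wrist Z}
#'   \item{vertical_head_move}{max - min of the relative head Y}
#'   \item{head_posture}{mean angle (radians) between the vertical and the
#'     neck-clavicle line projected on the Y-Z plane}
#'   \item{stride_left/right}{max - min of the relative foot Z}
#'   \item{toe_clearance_left/right}{max of the relative foot Y (see
#'     `toe_clearance_mode`)}
#'   \item{walking_speed}{|delta sensor-frame spine Z| / cycle duration, m/s}
#' }
#'
#' @param segment A `gait_segment`.
#' @param toe_clearance_mode "max" (default; matches the negative magnitudes
#'   a spine-relative foot height takes) or "range" (max - min).
#' @param degrees If TRUE, head_posture is reported in degrees.
#' @return Named numeric vector of length 10.
#' @export
spatiotemporal_features <- function(segment, toe_clearance_mode = c("max", "range"),
                                    degrees = FALSE) {
  toe_clearance_mode <- match.arg(toe_clearance_mode)
  per_cycle <- vapply(1:2, function(cy) {
    i <- cycle_frames(segment, cy)
    p <- segment$relative_positions
    rng <- function(v) max(v) - min(v)
    vy <- p[i, 2, 2] - p[i, 3, 2]
    vz <- p[i, 2, 3] - p[i, 3, 3]
    ang <- acos(pmin(1, abs(vy) / sqrt(vy^2 + vz^2)))
    tc <- if (toe_clearance_mode == "max") {
      c(max(p[i, 22, 2]), max(p[i, 23, 2]))
    } else {
      c(rng(p[i, 22, 2]), rng(p[i, 23, 2]))
    }
    # displacement between first and last cycle frame spans n-1 intervals
    dur <- (length(i) - 1) / segment$frame_rate
    c(body_sway = max(abs(p[i, 4, 1] - p[i, 5, 1])),
      arm_swing_left = rng(p[i, 10, 3]),
      arm_swing_right = rng(p[i, 14, 3]),
      vertical_head_move = rng(p[i, 1, 2]),
      head_posture = mean(ang),
      stride_left = rng(p[i, 22, 3]),
      stride_right = rng(p[i, 23, 3]),
      toe_clearance_left = tc[1],
      toe_clearance_right = tc[2],
      walking_speed = abs(segment$sensor_spine_z[i[length(i)]] -
                            segment$sensor_spine_z[i[1]]) / dur)
  }, numeric(10))
  out <- rowMeans(per_cycle)
  if (degrees) out["head_posture"] <- out["head_posture"] * 180 / pi
  out
}

channel_grid <- function() {
  expand.grid(axis = c("x", "y", "z"), joint = 1:25,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
}

#' Time-domain features (300)
#'
#' [moment_stats()] applied to each of the 75 spine-relative channels
#' (25 joints x 3 axes): 4 statistics per channel.
#'
#' @param segment A `gait_segment`.
#' @return Named numeric vector of length 300 (`t.j<joint>.<axis>.<stat>`).
#' @export
time_domain_features <- function(segment) {
  grid <- channel_grid()
  out <- unlist(lapply(seq_len(nrow(grid)), function(r) {
    ms <- moment_stats(seg_channel(segment, grid$joint[r], grid$axis[r]))
    stats::setNames(ms, sprintf("t.j%02d.%s.%s", grid$joint[r], grid$axis[r],
                                names(ms)))
  }))
  stopifnot(length(out) == 300L)
  out
}

freq_channel_stats <- function(x) {
  sp <- dft(x)
  stat10 <- function(v, label) {
    ms <- moment_stats(v)
    stats::setNames(c(ms["mean"], var = ms[["sd"]]^2, ms["sd"],
                      ms["skewness"], ms["kurtosis"]),
                    paste0(label, ".", c("mean", "var", "sd", "skewness",
                                         "kurtosis")))
  }
  c(dc = sp$dc, stat10(sp$amplitudes, "amp"), stat10(sp$phases, "phase"))
}

#' Frequency-domain features (825)
#'
#' Per channel: the DC component (signal mean) plus mean, variance, SD,
#' skewness and kurtosis of the DFT amplitudes and of the phases over
#' k = 1..n-1, i.e. 11 features per channel, 75 channels.
#'
#' @param segment A `gait_segment`.
#' @return Named numeric vector of length 825 (`f.j<joint>.<axis>.<stat>`).
#' @export
frequency_domain_features <- function(segment) {
  grid <- channel_grid()
  out <- unlist(lapply(seq_len(nrow(grid)), function(r) {
    fs <- freq_channel_stats(seg_channel(segment, grid$joint[r], grid$axis[r]))
    stats::setNames(fs, sprintf("f.j%02d.%s.%s", grid$joint[r], grid$axis[r],
                                names(fs)))
  }))
  stopifnot(length(out) == 825L)
  out
}

#' Extract all three feature banks from a segment
#'
#' @param segment A `gait_segment`.
#' @param blocks Subset of c("spatiotemporal", "time", "frequency").
#' @return Named numeric vector with a `block` attribute (character vector
#'   labeling each feature's bank); lengths 10 / 300 / 825 per block.
#' @export
extract_features <- function(segment,
                             blocks = c("spatiotemporal", "time", "frequency")) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  vals <- numeric(0)
  lab <- character(0)
  if ("spatiotemporal" %in% blocks) {
    v <- spatiotemporal_features(segment)
    vals <- c(vals, v); lab <- c(lab, rep("spatiotemporal", length(v)))
  }
  if ("time" %in% blocks) {
    v <- time_domain_features(segment)
    vals <- c(vals, v); lab <- c(lab, rep("time", length(v)))
  }
  if ("frequency" %in% blocks) {
    v <- frequency_domain_features(segment)
    vals <- c(vals, v); lab <- c(lab, rep("frequency", length(v)))
  }
  attr(vals, "block") <- lab
  vals
}

#' Features as a long data.frame
#'
#' @param segment A `gait_segment`.
#' @inheritParams extract_features
#' @return data.frame `participant_id`, `feature`, `block`, `value`.
#' @export
feature_table <- function(segment,
                          blocks = c("spatiotemporal", "time", "frequency")) {
  v <- extract_features(segment, blocks)
  data.frame(participant_id = segment$participant_id,
             feature = names(v),
             block = attr(v, "block"),
             value = as.numeric(v),
             stringsAsFactors = FALSE)
}
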