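#' Default per-group kinematic means and SDs
#'
#' Group-level sampling distributions for the gait parameters of synthetic
#' walkers. Spatiotemporal means/SDs are the published case/control summary
#' statistics of a 247-participant clinical gait study (case group = people
#' with depression, control = healthy walkers); cycle duration is centred on
#' half the reported mean two-cycle segment length (2.37 s) with its SD
#' scaled accordingly, truncated to half the reported segment range
#' (1.73-3.43 s). The last four rows shape the oscillation waveform rather
#' than its excursion and carry the group differences that make time- and
#' frequency-domain features more informative than the stride-level
#' summaries: `harmonic_ratio`/`harmonic_phase` add second-harmonic content
#' (limb waveforms are renormalized to unit peak-to-peak, so these never
#' leak into the spatiotemporal amplitudes); `step_hitch` is the depth (m)
#' of a brief per-cycle transient on the wrist trajectories (a distribution
#' asymmetry mostly seen by the time-domain moments); `tremor_amp` is the
#' amplitude (m) of a 5 Hz narrowband tremor with random phase on hand and
#' head channels unused by any stride-level feature (an isolated spectral
#' line mostly seen by the amplitude statistics).
#'
#' @return A data.frame with columns `param`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`, `lower`, `upper` (truncation bounds).
#' @export
default_gait_param_table <- function() {
  tab <- rbind(
    c("body_sway",           0.36, 0.04, 0.36, 0.04, 0.05,  1.0),
    c("arm_swing_left",      0.27, 0.11, 0.31, 0.12, 0.01,  1.0),
    c("arm_swing_right",     0.23, 0.09, 0.27, 0.10, 0.01,  1.0),
    c("vertical_head_move",  0.06, 0.05, 0.06, 0.04, 0.005, 0.5),
    c("head_posture",        1.23, 0.10, 1.27, 0.06, 0.30,  1.55),
    c("stride_left",         0.62, 0.07, 0.62, 0.07, 0.10,  1.5),
    c("stride_right",        0.59, 0.08, 0.61, 0.07, 0.10,  1.5),
    c("toe_clearance_left",  -0.69, 0.06, -0.71, 0.06, -1.10, -0.20),
    c("toe_clearance_right", -0.70, 0.06, -0.71, 0.07, -1.10, -0.20),
    c("walking_speed",       0.99, 0.18, 1.01, 0.17, 0.20,  2.0),
    c("cycle_duration",      1.185, 0.13, 1.185, 0.13, 0.865, 1.715),
    c("harmonic_ratio",      0.15, 0.08, 0.08, 0.07, 0.0,   0.8),
    c("harmonic_phase",      0.60, 0.40, 0.40, 0.35, -3.1,  3.1),
    c("step_hitch",          0.026, 0.014, 0.012, 0.010, 0.0, 0.10),
    c("tremor_amp",          0.018, 0.006, 0.006, 0.004, 0.0, 0.05),
    c("gait_phase_lag",      0.80, 0.30, 0.30, 0.25, -0.5,  2.0)
  )
  df <- data.frame(param = tab[, 1], stringsAsFactors = FALSE)
  df$case_mean <- as.numeric(tab[, 2]); df$case_sd <- as.numeric(tab[, 3])
  df$control_mean <- as.numeric(tab[, 4]); df$control_sd <- as.numeric(tab[, 5])
  df$lower <- as.numeric(tab[, 6]); df$upper <- as.numeric(tab[, 7])
  df
}

#' Cohort configuration
#'
#' Defaults emulate the capture protocol of the clinical study every stage of
#' this package mirrors: 126 cases and 121 controls walking naturally back
#' and forth for 2 minutes on a 6 m footpath, sampled at 30 Hz.
#'
#' @param n_case,n_control Group sizes (defaults 126 / 121).
#' @param path_length Footpath length in meters (default 6).
#' @param duration Recording duration in seconds (default 120).
#' @param frame_rate Sampling rate in Hz (default 30).
#' @param seed Integer seed controlling all randomness.
#' @param param_table Per-group sampling table, see
#'   [default_gait_param_table()].
#' @param shape_effect Logical; if FALSE the waveform-shape parameters
#'   (`harmonic_ratio`, `harmonic_phase`) are forced to the control-group
#'   mean for both groups, leaving only stride-level group differences.
#' @param noise_sd Gaussian sensor noise SD in meters added to every channel
#'   (default 0.005, a typical depth-sensor jitter magnitude).
#' @param jitter_amplitude Amplitude (m) of a 13.7 Hz high-frequency jitter
#'   component with random per-channel phase (default 0.003).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_case = 126, n_control = 121,
                          path_length = 6, duration = 120,
                          frame_rate = 30, seed = 1,
                          param_table = default_gait_param_table(),
                          shape_effect = TRUE,
                          noise_sd = 0.005, jitter_amplitude = 0.003) {
  if (n_case < 0 || n_control < 0) stop("group sizes must be >= 0", call. = FALSE)
  if (path_length <= 0 || duration <= 0 || frame_rate <= 0) {
    stop("path_length, duration and frame_rate must be positive", call. = FALSE)
  }
  if (any(param_table$case_sd < 0) || any(param_table$control_sd < 0)) {
    stop("config error: negative SD in param_table", call. = FALSE)
  }
  cfg <- list(n_case = n_case, n_control = n_control,
              path_length = path_length, duration = duration,
              frame_rate = frame_rate, seed = as.integer(seed),
              param_table = param_table, shape_effect = shape_effect,
              noise_sd = noise_sd, jitter_amplitude = jitter_amplitude)
  class(cfg) <- "cohort_config"
  cfg
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  stop("truncated-normal rejection failed (bounds too tight?)", call. = FALSE)
}

#' Draw one walker's gait parameters for a group
#'
#' Each parameter is drawn independently from a truncated normal with the
#' group's mean/SD (truncation at physical bounds; SD 0 degenerates to the
#' mean exactly).
#'
#' @param group "case" or "control".
#' @param config A [cohort_config()].
#' @return Named list of gait parameters (class `gait_params`).
#' @export
sample_gait_params <- function(group = c("case", "control"),
                               config = cohort_config()) {
  group <- match.arg(group)
  pt <- config$param_table
  mu <- if (group == "case") pt$case_mean else pt$control_mean
  sd <- if (group == "case") pt$case_sd else pt$control_sd
  if (!config$shape_effect) {
    shape <- pt$param %in% c("harmonic_ratio", "harmonic_phase",
                             "step_hitch", "tremor_amp", "gait_phase_lag")
    mu[shape] <- pt$control_mean[shape]
    sd[shape] <- 0
  }
  p <- mapply(rtruncnorm1, mu, sd, pt$lower, pt$upper)
  names(p) <- pt$param
  out <- as.list(p)
  out$noise_sd <- config$noise_sd
  out$jitter_amplitude <- config$jitter_amplitude
  class(out) <- "gait_params"
  out
}

# Normalize an oscillation waveform to zero midpoint and unit peak-to-peak,
# so the configured amplitude is exactly the max-min excursion regardless of
# harmonic content. f(phi) = sin(phi) + r * sin(2 phi + ph).
norm_osc <- function(phi, r, ph) {
  grid <- seq(0, 2 * pi, length.out = 721)
  g <- sin(grid) + r * sin(2 * grid + ph)
  lo <- min(g); hi <- max(g)
  (sin(phi) + r * sin(2 * phi + ph) - (hi + lo) / 2) / (hi - lo)
}

#' Synthesize one skeleton walking recording
#'
#' Kinematic model: a constant-speed spine trajectory ping-pongs along the
#' footpath (Z decreasing on face-toward passes, increasing on back-toward
#' passes); every other joint is a fixed anatomical offset from the spine
#' plus a sinusoidal oscillator at the gait frequency. Arm and leg
#' oscillators on the same side are in antiphase; waveforms are normalized
#' to unit peak-to-peak so amplitude parameters equal the max-min excursion
#' they induce. The left-toe vertical trajectory has one sharp minimum per
#' cycle at the cycle start (the toe-off event used downstream). Gaussian
#' sensor noise and a high-frequency jitter tone are added to all 75
#' channels.
#'
#' @param params A `gait_params` list from [sample_gait_params()].
#' @param config A [cohort_config()].
#' @param participant_id,group_label Metadata attached to the recording.
#' @return A sensor-frame [skeleton_recording()].
#' @export
synthesize_recording <- function(params, config = cohort_config(),
                                 participant_id = "synthetic",
                                 group_label = NA) {
  L <- config$path_length
  speed <- params$walking_speed
  if (config$duration < 2 * L / speed) {
    stop("config error: duration too short for two walking passes",
         call. = FALSE)
  }
  fps <- config$frame_rate
  tt <- round(config$duration * fps)
  t <- (seq_len(tt) - 1) / fps

  # spine: triangle wave between z_near and z_far, starting at z_far walking
  # toward the sensor
  z_near <- 0.8
  u <- (speed * t) %% (2 * L)
  d <- ifelse(u < L, u, 2 * L - u)
  spine <- cbind(x = rep(0, tt), y = 0.90 + 0.01 * sin(4 * pi * t / params$cycle_duration),
                 z = z_near + L - d)

  # all limb/trunk oscillators run at a participant-specific phase lag
  # relative to the toe-off-anchored gait cycle (the left-toe trajectory
  # that defines cycle starts is NOT lagged). Over whole cycles the lag
  # leaves every time-domain marginal and every max-min excursion
  # untouched; only the spectral phases move.
  phi0 <- 2 * pi * t / params$cycle_duration
  phi <- phi0 + params$gait_phase_lag
  r <- params$harmonic_ratio
  ph <- params$harmonic_phase
  osc  <- function(offset) norm_osc(phi + offset, r, ph)
  lift <- function(offset) 0.5 - norm_osc(phi + offset, r, ph)  # in [0, 1]

  rel <- array(0, dim = c(tt, 25, 3))
  set_rel <- function(j, x, y, z) {
    rel[, j, 1] <<- x; rel[, j, 2] <<- y; rel[, j, 3] <<- z
  }

  bs <- params$body_sway
  th <- params$head_posture
  # fixed-amplitude postural wobble at the gait frequency on lateral hand
  # and head channels (identical for all walkers); the 5 Hz tremor rides on
  # these channels, where its variance contribution is masked by the wobble
  # but its spectral line remains isolated
  wob <- function(offset) 0.12 * sin(phi + offset)
  # vertical head bounce at the gait frequency (kept at the fundamental so
  # the five-point filter attenuates its peak-to-peak by under 2 %)
  set_rel(1, wob(0.4), 0.62 + params$vertical_head_move *
            (sin(phi + 0.7) / 2), 0.02 + wob(2.1))
  # clavicle fixed; neck placed so the clavicle->neck line makes angle th
  # with the vertical in the Y-Z plane
  neck_len <- 0.12
  set_rel(3, 0, 0.45, 0)                                   # clavicle
  set_rel(2, 0, 0.45 + neck_len * cos(th), neck_len * sin(th))  # neck
  # shoulders: constant separation bs - 0.02 plus antisymmetric sway of
  # amplitude 0.01 each, so max |xL - xR| = bs exactly
  sway <- 0.01 * sin(phi)
  set_rel(4,  (bs - 0.02) / 2 + sway, 0.42, 0)
  set_rel(5, -(bs - 0.02) / 2 - sway, 0.42, 0)
  # arms: wrist Z oscillates with the configured peak-to-peak swing;
  # left arm phase 0, right arm antiphase. A brief per-cycle transient
  # ("hitch") of depth step_hitch is added mid-flank (phase 3.0 rad, width
  # 0.25 rad), where it cannot extend the max-min excursion.
  bump <- function(center) {
    dphi <- ((phi - center) %% (2 * pi))
    dphi <- pmin(dphi, 2 * pi - dphi)
    exp(-dphi^2 / (2 * 0.25^2))
  }
  wzl <- params$arm_swing_left  * osc(0)  - params$step_hitch * bump(3.0)
  wzr <- params$arm_swing_right * osc(pi) - params$step_hitch * bump(3.0 + pi)
  set_rel(10,  0.30 + wob(0.9), -0.05, wzl)   # wrist_left
  set_rel(14, -0.30 + wob(4.0), -0.05, wzr)   # wrist_right
  set_rel(6,   0.28,  0.18, 0.5 * wzl)      # elbow_left
  set_rel(7,  -0.28,  0.18, 0.5 * wzr)      # elbow_right
  set_rel(8,   0.31 + wob(1.6), -0.12, 1.05 * wzl)  # hand_left
  set_rel(11, -0.31 + wob(5.2), -0.12, 1.05 * wzr)  # hand_right
  set_rel(12,  0.33, -0.10, 1.02 * wzl)     # thumb_left
  set_rel(13, -0.33, -0.10, 1.02 * wzr)     # thumb_right
  # trunk / pelvis
  set_rel(21, 0, -0.30, 0)                  # spine_base
  set_rel(15,  0.12, -0.35, 0)              # hip_left
  set_rel(16, -0.12, -0.35, 0)              # hip_right
  # legs: left leg antiphase to left arm; feet carry stride (Z) and
  # clearance (Y); Y maximum equals the toe-clearance parameter exactly
  fzl <- params$stride_left  * osc(pi) - params$step_hitch * bump(3.0 + pi)
  fzr <- params$stride_right * osc(0)  - params$step_hitch * bump(3.0)
  lift_amp <- 0.10
  fyl <- params$toe_clearance_left  - lift_amp * lift(pi)
  fyr <- params$toe_clearance_right - lift_amp * lift(0)
  set_rel(17,  0.12, -0.62, 0.55 * fzl)     # knee_left
  set_rel(18, -0.12, -0.62, 0.55 * fzr)     # knee_right
  set_rel(19,  0.12, fyl + 0.06, 0.95 * fzl)  # ankle_left
  set_rel(20, -0.12, fyr + 0.06, 0.95 * fzr)  # ankle_right
  set_rel(22,  0.12, fyl, fzl)              # foot_left
  set_rel(23, -0.12, fyr, fzr)              # foot_right
  # toes: left toe Y has one cusp-like minimum per cycle at phi0 = 0 (mod
  # 2 pi) -- the toe leaves the ground abruptly, which pins the detected
  # toe-off to the cycle start even under noise; kept free of harmonic
  # shaping and of the phase lag so cycle boundaries stay exact
  set_rel(24,  0.14, -0.74 + 0.06 * abs(sin(phi0 / 2)), fzl * 1.02)
  set_rel(25, -0.14, -0.74 + 0.06 * abs(cos(phi0 / 2)), fzr * 1.02)

  # narrowband 5 Hz tremor on the wobble channels (wrist X, hand X,
  # head X/Z) -- none is read by any stride-level feature; random phase per
  # channel
  if (params$tremor_amp > 0) {
    trem_ch <- rbind(c(10, 1), c(14, 1), c(8, 1), c(11, 1),
                     c(1, 1), c(1, 3))
    for (rix in seq_len(nrow(trem_ch))) {
      rel[, trem_ch[rix, 1], trem_ch[rix, 2]] <-
        rel[, trem_ch[rix, 1], trem_ch[rix, 2]] +
        params$tremor_amp * sin(2 * pi * 5 * t + stats::runif(1, 0, 2 * pi))
    }
  }

  pos <- rel
  pos[, , 1] <- pos[, , 1] + spine[, 1]
  pos[, , 2] <- pos[, , 2] + spine[, 2]
  pos[, , 3] <- pos[, , 3] + spine[, 3]
  pos[, 9, 1] <- spine[, 1]; pos[, 9, 2] <- spine[, 2]; pos[, 9, 3] <- spine[, 3]

  if (params$noise_sd > 0) {
    pos <- pos + stats::rnorm(length(pos), 0, params$noise_sd)
  }
  if (params$jitter_amplitude > 0) {
    phase <- stats::runif(75, 0, 2 * pi)
    jit <- params$jitter_amplitude *
      sin(outer(2 * pi * 13.7 * t, rep(1, 75)) +
            matrix(phase, tt, 75, byrow = TRUE))
    pos <- pos + array(jit, dim = dim(pos))
  }
  skeleton_recording(pos, frame_rate = fps, participant_id = participant_id,
                     group_label = group_label, coordinate_frame = "sensor")
}

#' Generate a labeled synthetic cohort
#'
#' Draws per-participant gait parameters and synthesizes one recording per
#' participant; cases first, then controls. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return List with elements `recordings` (list of
#'   [skeleton_recording()]s) and `labels` (integer vector, 1 = case).
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  labels <- c(rep(1L, config$n_case), rep(0L, config$n_control))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- if (labels[i] == 1L) "case" else "control"
    id <- sprintf("%s_%03d", grp, if (grp == "case") i else i - config$n_case)
    p <- sample_gait_params(grp, config)
    recs[[i]] <- synthesize_recording(p, config, participant_id = id,
                                      group_label = labels[i])
  }
  list(recordings = recs, labels = labels)
}
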