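# shared fixture builders; everything is generated in code at test time

# a small, fast cohort configuration for unit tests
tiny_config <- function(seed = 101, ...) {
  cohort_config(n_case = 4, n_control = 4, duration = 30, seed = seed, ...)
}

# fully deterministic walker: no sensor noise, no jitter, no waveform-shape
# components; overrides applied on top
noiseless_params <- function(seed = 7, group = "control", ...) {
  set.seed(seed)
  p <- sample_gait_params(group, cohort_config(shape_effect = FALSE))
  p$noise_sd <- 0
  p$jitter_amplitude <- 0
  p$step_hitch <- 0
  p$tremor_amp <- 0
  p$harmonic_ratio <- 0
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p
}

# build a gait_segment directly from a relative-position array
manual_segment <- function(rel, spine_z = NULL, frame_rate = 30,
                           boundaries = NULL) {
  tt <- dim(rel)[1]
  if (is.null(boundaries)) boundaries <- c(0L, tt %/% 2L, tt)
  if (is.null(spine_z)) spine_z <- rep(0, tt)
  structure(list(relative_positions = rel, sensor_spine_z = spine_z,
                 frame_rate = frame_rate, cycle_boundaries = boundaries,
                 duration_s = tt / frame_rate,
                 participant_id = "manual", group_label = NA),
            class = "gait_segment")
}

# a segment with every joint frozen at a standing pose (zero motion)
static_segment <- function(tt = 64, spine_z = rep(5, tt)) {
  rel <- array(0, dim = c(tt, 25, 3))
  rel[, 2, 2] <- 0.57   # neck directly above clavicle
  rel[, 3, 2] <- 0.45
  rel[, 1, 2] <- 0.62
  manual_segment(rel, spine_z = spine_z)
}

# a preprocessed noiseless walker segment (cached per session)
noiseless_segment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- noiseless_params(seed = 7)
      rec <- synthesize_recording(p, cohort_config(), participant_id = "nl")
      cache <<- list(params = p, segment = preprocess_recording(rec))
    }
    cache
  }
})
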