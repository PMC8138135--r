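make_rec <- function(pos, fps = 30) {
  skeleton_recording(pos, frame_rate = fps, participant_id = "t")
}

test_that("spine-relative transform zeroes the spine and is translation invariant", {
  tt <- 20
  pos <- array(rnorm(tt * 25 * 3), dim = c(tt, 25, 3))
  # all joints at the spine position -> all-zero relative output
  same <- pos
  for (j in 1:25) same[, j, ] <- pos[, 9, ]
  rel <- to_spine_relative(make_rec(same))
  expect_true(all(rel$positions == 0))
  expect_equal(rel$coordinate_frame, "spine_relative")
  expect_equal(rel$sensor_spine, pos[, 9, ], ignore_attr = TRUE)

  # global translation leaves the relative frame unchanged
  shifted <- pos
  shifted[, , 1] <- shifted[, , 1] + 1
  shifted[, , 2] <- shifted[, , 2] + 2
  shifted[, , 3] <- shifted[, , 3] + 3
  expect_equal(to_spine_relative(make_rec(pos))$positions,
               to_spine_relative(make_rec(shifted))$positions)

  expect_error(to_spine_relative(rel), "already spine-relative")
})

test_that("the Gaussian kernel and filter behave as a unit-gain low-pass", {
  expect_equal(gaussian_kernel(), c(1, 4, 6, 4, 1) / 16)
  expect_equal(sum(gaussian_kernel()), 1)
  # constant in, constant out
  expect_equal(gaussian_filter(rep(3.2, 40)), rep(3.2, 40))
  # impulse response
  expect_equal(gaussian_filter(c(0, 0, 1, 0, 0)),
               c(1, 4, 6, 4, 1) / 16)
  expect_error(gaussian_filter(1:4), "length >= 5")
})

test_that("filtering equals a direct convolution sum with replicated edges", {
  brute <- function(x) {
    n <- length(x)
    k <- c(1, 4, 6, 4, 1) / 16
    sapply(seq_len(n), function(i) {
      s <- 0
      for (o in -2:2) s <- s + k[o + 3] * x[min(max(i + o, 1), n)]
      s
    })
  }
  set.seed(5)
  for (rep in 1:100) {
    x <- rnorm(sample(5:40, 1))
    expect_equal(gaussian_filter(x), brute(x), tolerance = 1e-12)
  }
})

test_that("the filter is linear and attenuates the Nyquist frequency", {
  set.seed(6)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(gaussian_filter(2 * x - 3 * y),
               2 * gaussian_filter(x) - 3 * gaussian_filter(y),
               tolerance = 1e-12)
  nyq <- rep(c(1, -1), 25)
  expect_lt(diff(range(gaussian_filter(nyq)[3:48])), 0.01 * diff(range(nyq)))
})

test_that("walk passes split on the sign of the smoothed spine-Z velocity", {
  tt <- 300
  mk <- function(z) {
    pos <- array(0, dim = c(tt, 25, 3))
    pos[, 9, 3] <- z
    make_rec(pos)
  }
  # monotone decreasing -> one toward pass covering everything
  p1 <- split_walk_passes(mk(seq(8, 2, length.out = tt)))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$direction, "toward")
  expect_equal(c(p1$start, p1$end), c(0L, tt))
  # triangle wave with 2 round trips -> 2 toward + 2 away
  z <- 5 + 2 * abs(seq(-1, 3, length.out = tt) %% 2 - 1)
  p2 <- split_walk_passes(mk(z))
  expect_equal(sum(p2$direction == "toward"), 2L)
  expect_equal(sum(p2$direction == "away"), 2L)
  # passes disjoint and ordered
  expect_true(all(p2$end[-nrow(p2)] == p2$start[-1]))
  # no toward pass
  expect_error(split_walk_passes(mk(seq(2, 8, length.out = tt))),
               "no face-toward pass")
})

test_that("the middle face-toward pass is selected with an earlier tie-break", {
  mk <- function(k) {
    data.frame(start = seq(0, by = 100, length.out = 2 * k),
               end = seq(100, by = 100, length.out = 2 * k),
               direction = rep(c("toward", "away"), k))
  }
  expect_equal(select_middle_face_toward(mk(1))$start, 0)
  expect_equal(select_middle_face_toward(mk(3))$start, 200)   # 2nd of 3
  expect_equal(select_middle_face_toward(mk(4))$start, 200)   # 2nd of 4
})

test_that("toe-off detection finds analytic minima and survives noise", {
  fps <- 30
  t <- (0:299) / fps
  y <- -0.7 - 0.05 * cos(2 * pi * t / 1.2)   # minima every 36 frames
  ev <- detect_toe_off_events(gaussian_filter(y), fps)
  expect_equal(diff(ev), rep(36, length(ev) - 1))

  set.seed(9)
  noisy <- y + rnorm(length(y), 0, 0.004)
  ev2 <- detect_toe_off_events(gaussian_filter(noisy), fps)
  expect_equal(length(ev2), length(ev))
  expect_true(all(abs(ev2 - ev) <= 3))

  expect_error(detect_toe_off_events(rep(-0.7, 300), fps),
               "insufficient gait cycles")
})

test_that("two-cycle extraction crops between the central toe-off events", {
  tt <- 200
  pos <- array(rnorm(tt * 25 * 3, sd = 0.01), dim = c(tt, 25, 3))
  rel <- to_spine_relative(make_rec(pos))
  seg <- extract_two_cycle_segment(rel, events = c(10L, 46L, 82L))
  expect_equal(length(seg$sensor_spine_z), 72L)
  expect_equal(seg$cycle_boundaries, c(0L, 36L, 72L))
  expect_equal(seg$duration_s, 72 / 30)
  expect_error(extract_two_cycle_segment(rel, events = c(10L, 46L)),
               "insufficient gait cycles")
})

test_that("preprocessing a noiseless walker recovers the cycle duration within one frame", {
  for (cd in c(1.0, 1.2, 1.5)) {
    p <- noiseless_params(seed = 13, cycle_duration = cd)
    rec <- synthesize_recording(p, cohort_config(duration = 60))
    seg <- preprocess_recording(rec)
    expect_lt(abs(seg$duration_s / 2 - cd), 1 / 30)
    expect_equal(seg$cycle_boundaries[3],
                 as.integer(length(seg$sensor_spine_z)))
  }
})

test_that("preprocessing commutes with a global sensor-frame translation", {
  p <- noiseless_params(seed = 17)
  rec <- synthesize_recording(p, cohort_config(duration = 40))
  shifted <- rec
  shifted$positions[, , 1] <- shifted$positions[, , 1] + 0.5
  shifted$positions[, , 2] <- shifted$positions[, , 2] - 0.2
  s1 <- preprocess_recording(rec)
  s2 <- preprocess_recording(shifted)
  expect_equal(s1$relative_positions, s2$relative_positions)
  expect_equal(s1$cycle_boundaries, s2$cycle_boundaries)
})
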