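test_that("feature banks have exactly 10 / 300 / 825 uniquely named features", {
  for (seed in c(7, 19)) {
    p <- noiseless_params(seed = seed)
    rec <- synthesize_recording(p, cohort_config(duration = 40))
    seg <- preprocess_recording(rec)
    st <- spatiotemporal_features(seg)
    tm <- time_domain_features(seg)
    fq <- frequency_domain_features(seg)
    expect_length(st, 10L)
    expect_length(tm, 300L)
    expect_length(fq, 825L)
    expect_false(anyDuplicated(c(names(st), names(tm), names(fq))) > 0)
    expect_true(all(is.finite(c(st, tm, fq))))
  }
})

test_that("spatiotemporal features recover generator parameters on noiseless walkers", {
  nl <- noiseless_segment()
  p <- nl$params
  f <- spatiotemporal_features(nl$segment)
  target <- c(body_sway = p$body_sway,
              arm_swing_left = p$arm_swing_left,
              arm_swing_right = p$arm_swing_right,
              vertical_head_move = p$vertical_head_move,
              head_posture = p$head_posture,
              stride_left = p$stride_left,
              stride_right = p$stride_right,
              toe_clearance_left = p$toe_clearance_left,
              toe_clearance_right = p$toe_clearance_right,
              walking_speed = p$walking_speed)
  for (nm in names(target)) {
    expect_lt(abs(f[[nm]] - target[[nm]]) / abs(target[[nm]]), 0.05,
              label = sprintf("%s relative error", nm))
  }
  # arm swing only suffers the small filter attenuation (< 2 %)
  expect_lt(abs(f[["arm_swing_left"]] - p$arm_swing_left) /
              p$arm_swing_left, 0.02)
})

test_that("a static pose yields zero excursions, zero speed, zero head angle", {
  seg <- static_segment()
  f <- spatiotemporal_features(seg)
  zero_feats <- c("arm_swing_left", "arm_swing_right", "vertical_head_move",
                  "stride_left", "stride_right", "walking_speed", "body_sway")
  expect_equal(unname(f[zero_feats]), rep(0, length(zero_feats)))
  # neck exactly above clavicle -> no tilt
  expect_equal(f[["head_posture"]], 0)
})

test_that("moment statistics match a direct central-moment computation", {
  expect_equal(moment_stats(c(1, 1, 1, 1)),
               c(mean = 1, sd = 0, skewness = 0, kurtosis = 0))
  expect_equal(moment_stats(c(-1, 0, 1, 0))[["skewness"]], 0)
  x <- c(0, 1, 2, 9)
  m <- mean(x); d <- x - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  expect_equal(moment_stats(x),
               c(mean = m, sd = sd(x), skewness = m3 / m2^1.5,
                 kurtosis = m4 / m2^2 - 3))
  expect_error(moment_stats(1:3), "length >= 4")
})

test_that("time-domain features are per-channel moments with degenerate channels at zero", {
  seg <- static_segment()
  tm <- time_domain_features(seg)
  expect_length(tm, 300L)
  expect_equal(tm[["t.j02.y.mean"]], 0.57)
  expect_true(all(tm[grepl("\\.(sd|skewness|kurtosis)$", names(tm))] == 0))
})

test_that("permuting joints permutes time-domain values under renamed features", {
  set.seed(23)
  rel <- array(rnorm(60 * 25 * 3), dim = c(60, 25, 3))
  seg <- manual_segment(rel)
  perm <- sample(25)
  seg2 <- manual_segment(rel[, perm, , drop = FALSE])
  t1 <- time_domain_features(seg)
  t2 <- time_domain_features(seg2)
  expect_equal(sort(unname(t1)), sort(unname(t2)))
  # a specific channel moves to its permuted name
  expect_equal(unname(t2[sprintf("t.j%02d.x.mean", 1)]),
               unname(t1[sprintf("t.j%02d.x.mean", perm[1])]))
})

test_that("the DFT matches a brute-force O(n^2) transform", {
  brute <- function(x) {
    n <- length(x)
    f <- vapply(0:(n - 1), function(k) {
      sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
    }, complex(1))
    list(dc = Re(f[1]) / n, amplitudes = Mod(f[-1]), phases = Arg(f[-1]))
  }
  set.seed(31)
  for (n in c(2, 7, 16, 33, 70)) {
    x <- rnorm(n)
    got <- dft(x)
    want <- brute(x)
    expect_equal(got$dc, want$dc, tolerance = 1e-10)
    expect_equal(got$amplitudes, want$amplitudes, tolerance = 1e-9)
    # compare phases only where the amplitude is numerically meaningful
    big <- want$amplitudes > 1e-8
    expect_equal(got$phases[big], want$phases[big], tolerance = 1e-8)
  }
})

test_that("DFT identities: DC is the mean, single tone concentrates, Parseval holds", {
  expect_equal(dft(rep(2.5, 8))$dc, 2.5)
  expect_true(all(dft(rep(2.5, 8))$amplitudes < 1e-12))

  n <- 16
  x <- cos(2 * pi * (0:(n - 1)) / n)
  sp <- dft(x)
  expect_equal(sp$amplitudes[c(1, n - 1)], c(n / 2, n / 2), tolerance = 1e-10)
  expect_true(all(sp$amplitudes[-c(1, n - 1)] < 1e-10))

  set.seed(37)
  for (rep in 1:20) {
    z <- rnorm(sample(8:64, 1))
    f <- fft(z)
    expect_equal(sum(z^2), sum(Mod(f)^2) / length(z), tolerance = 1e-9)
  }
})

test_that("frequency-domain features compose moment stats over the spectrum", {
  seg <- static_segment()
  fq <- frequency_domain_features(seg)
  expect_length(fq, 825L)
  expect_equal(fq[["f.j02.y.dc"]], 0.57)
  expect_true(all(fq[grepl("amp\\.", names(fq))][
    grepl("j02", names(fq[grepl("amp\\.", names(fq))]))] == 0))

  set.seed(41)
  rel <- array(rnorm(48 * 25 * 3), dim = c(48, 25, 3))
  seg2 <- manual_segment(rel)
  fq2 <- frequency_domain_features(seg2)
  sp <- dft(rel[, 5, 1])
  ms <- moment_stats(sp$amplitudes)
  expect_equal(fq2[["f.j05.x.amp.mean"]], ms[["mean"]])
  expect_equal(fq2[["f.j05.x.amp.sd"]], ms[["sd"]])
  expect_equal(fq2[["f.j05.x.amp.var"]], ms[["sd"]]^2)
  expect_equal(fq2[["f.j05.x.amp.kurtosis"]], ms[["kurtosis"]])
  expect_equal(fq2[["f.j05.x.dc"]], mean(rel[, 5, 1]))
})

test_that("translation and circular-shift invariances hold", {
  set.seed(43)
  rel <- array(rnorm(50 * 25 * 3), dim = c(50, 25, 3))
  seg <- manual_segment(rel)
  shifted <- rel; shifted[, 7, 2] <- shifted[, 7, 2] + 5
  segs <- manual_segment(shifted)
  t1 <- time_domain_features(seg); t2 <- time_domain_features(segs)
  expect_equal(t2[["t.j07.y.mean"]], t1[["t.j07.y.mean"]] + 5)
  for (stat in c("sd", "skewness", "kurtosis")) {
    expect_equal(t2[[paste0("t.j07.y.", stat)]],
                 t1[[paste0("t.j07.y.", stat)]])
  }
  # circular shift: amplitudes invariant
  x <- rnorm(40)
  xs <- c(x[31:40], x[1:30])
  expect_equal(dft(xs)$amplitudes, dft(x)$amplitudes, tolerance = 1e-9)
})

test_that("feature extraction labels blocks and produces a tidy table", {
  seg <- noiseless_segment()$segment
  v <- extract_features(seg)
  expect_length(v, 1135L)
  expect_equal(unname(table(attr(v, "block"))[c("spatiotemporal", "time", "frequency")]),
               c(10L, 300L, 825L), ignore_attr = TRUE)
  tab <- feature_table(seg, blocks = "spatiotemporal")
  expect_equal(nrow(tab), 10L)
  expect_equal(unique(tab$block), "spatiotemporal")
})
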