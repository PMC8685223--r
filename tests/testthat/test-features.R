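test_that("strap-down integration matches analytic velocities", {
  dt <- 1 / 200
  n <- 201L
  expect_equal(integrate_motion_velocity(matrix(0, n, 3L), dt),
               matrix(0, n, 3L))
  # constant 1 m/s^2 for 1 s -> 1 m/s
  a <- cbind(rep(1, n), 0, 0)
  v <- integrate_motion_velocity(a, dt)
  expect_equal(v[n, 1L], 1, tolerance = 1e-6)
  # half-sine pulse: v(t) = (A*T/pi) * (1 - cos(pi t / T)) / ... analytic
  t <- (seq_len(n) - 1) * dt
  A <- 2; Tp <- 1
  a2 <- cbind(A * sin(pi * t / Tp), 0, 0)
  v2 <- integrate_motion_velocity(a2, dt)
  v_true <- A * Tp / pi * (1 - cos(pi * t / Tp))
  expect_equal(v2[, 1L], v_true, tolerance = 1e-3 * max(v_true))
  expect_error(integrate_motion_velocity(matrix(0, 0L, 3L), dt), "empty")
})

test_that("drift correction enforces the zero-end-velocity constraint", {
  dt <- 1 / 200; n <- 141L
  t <- (seq_len(n) - 1) * dt
  # drift-free velocity ending at zero is untouched
  v <- cbind(sin(pi * t / t[n]), 0, 0)
  v[n, 1L] <- 0
  cv <- correct_velocity_drift(v, dt)
  expect_equal(cv$v, v, tolerance = 1e-12)
  # pure linear drift cancels exactly
  vd <- cbind(0.3 * t, -0.1 * t, 0.05 * t)
  cv2 <- correct_velocity_drift(vd, dt)
  expect_equal(max(abs(cv2$v)), 0, tolerance = 1e-12)
  expect_equal(cv2$stride_length, 0, tolerance = 1e-12)
})

test_that("polynomial velocity plus linear drift is recovered exactly", {
  dt <- 1 / 200; n <- 141L
  t <- (seq_len(n) - 1) * dt
  T_ <- t[n]
  # any polynomial velocity with v(end) = 0, contaminated by c * t
  v_true <- cbind(t * (T_ - t) * (1 + 2 * t), (t^2) * (T_ - t), 0)
  v_true[n, ] <- 0
  drift <- cbind(0.4 * t, -0.2 * t, 0.1 * t)
  cv <- correct_velocity_drift(v_true + drift, dt)
  expect_equal(cv$v, v_true, tolerance = 1e-9)
})

test_that("integration + correction is exact for linear acceleration + bias", {
  dt <- 1 / 200; n <- 141L
  t <- (seq_len(n) - 1) * dt
  T_ <- t[n]
  # a(t) = c0 + c1 t chosen so the true velocity returns to zero at T
  c1 <- 3; c0 <- -c1 * T_ / 2
  bias <- 0.05
  a <- cbind(c0 + c1 * t + bias, 0, 0)
  v_true <- c0 * t + c1 * t^2 / 2
  cv <- correct_velocity_drift(integrate_motion_velocity(a, dt), dt)
  expect_equal(cv$v[, 1L], v_true, tolerance = 1e-9)
})

test_that("turning detection follows the yaw contract", {
  deg <- pi / 180
  ramp <- seq(0, 45, length.out = 100) * deg
  r <- detect_turning(ramp)
  expect_identical(r$turned_flag, 1L)
  expect_equal(r$turning_angle, 45 * deg)

  zigzag <- c(seq(0, 10, length.out = 50), seq(10, -5, length.out = 50)) * deg
  z <- detect_turning(zigzag)
  expect_identical(z$turned_flag, 0L)
  expect_equal(z$turning_angle, -5 * deg)

  # straight walking with 0.3 deg yaw noise: flagged in < 5 % of phases
  set.seed(7)
  flags <- vapply(1:200, function(i)
    detect_turning(rnorm(140, 0, 0.3 * deg))$turned_flag, integer(1))
  expect_lte(mean(flags), 0.05)
})

test_that("stride of a synthetic step is recovered and yaw-invariant", {
  sim <- simulate_recording(list(list(mode = "normal", n_steps = 3)),
                            seed = 3, noise = FALSE)
  ft <- extract_feature_table(segment_recording(sim$series))
  expect_equal(nrow(ft), 3L)
  expect_equal(ft$stride_length, rep(0.6, 3L), tolerance = 0.01)
  expect_equal(ft$step_duration, sim$truth$steps$swing_duration,
               tolerance = 0.06)

  # heading-drift insensitivity: rotate the whole world about z
  rot <- 57 * pi / 180
  Rz <- matrix(c(cos(rot), -sin(rot), 0, sin(rot), cos(rot), 0, 0, 0, 1),
               3L, byrow = TRUE)
  # rotating sensor-frame inputs is equivalent to a yaw-rotated mounting
  s2 <- sim$series
  s2$acc <- t(Rz %*% t(s2$acc))
  s2$gyro <- t(Rz %*% t(s2$gyro))
  ft2 <- extract_feature_table(segment_recording(s2))
  expect_equal(ft2$stride_length, ft$stride_length, tolerance = 1e-2)
})

test_that("feature extraction is deterministic and time-translation invariant", {
  sim <- simulate_recording(list(list(mode = "normal", n_steps = 2)), seed = 9)
  ps <- segment_recording(sim$series)
  mp <- ps$motion[1L, ]
  seg <- ps$trace[ps$trace$t >= mp$t_start & ps$trace$t <= mp$t_end, ]
  f1 <- extract_features(seg, mp$t_start, mp$t_end, ps$fs)
  f2 <- extract_features(seg, mp$t_start, mp$t_end, ps$fs)
  expect_identical(f1, f2)
  expect_identical(names(f1), feature_names())
  # shifting the segment in time changes nothing but the metadata
  seg3 <- seg; seg3$t <- seg3$t + 11
  f3 <- extract_features(seg3, mp$t_start + 11, mp$t_end + 11, ps$fs)
  expect_equal(f3, f1, tolerance = 1e-12)
  expect_error(extract_features(seg, mp$t_start + 1, mp$t_end - 1, ps$fs),
               "mismatch")
})

test_that("a stationary segment with a single pitch peak yields that peak", {
  fs <- 200; n <- 101L
  t <- (seq_len(n) - 1) / fs
  deg <- pi / 180
  seg <- data.frame(t = t, adgx = 0, adgy = 0, adgz = 0,
                    pitch_d = 20 * deg * exp(-((t - 0.25)^2) / 0.01),
                    roll_d = 0, yaw_d = 0)
  f <- extract_features(seg, 0, t[n], fs)
  expect_equal(unname(f["max_pitch"]), 20 * deg, tolerance = 1e-6)
  expect_equal(unname(f["stride_length"]), 0, tolerance = 1e-9)
})

test_that("shuffling mode reduces pitch range and stride length", {
  simN <- simulate_recording(list(list(mode = "normal", n_steps = 8)),
                             seed = 11)
  simS <- simulate_recording(list(list(mode = "shuffling", n_steps = 8)),
                             seed = 11)
  fN <- extract_feature_table(segment_recording(simN$series))
  fS <- extract_feature_table(segment_recording(simS$series))
  expect_lt(stats::median(fS$max_pitch), stats::median(fN$max_pitch))
  expect_lt(stats::median(fS$stride_length), stats::median(fN$stride_length))
})

test_that("chi-square ranking matches hand-computed tables", {
  # 2x2 table a=30 b=10 / c=10 d=30: chi-square = 20, df = 1
  x <- rep(c(0, 1), each = 40)
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  r <- rank_features(data.frame(f = x), y)
  expect_equal(r$chi_sq, 20, tolerance = 1e-12)
  expect_equal(r$importance, -log10(stats::pchisq(20, 1, lower.tail = FALSE)),
               tolerance = 1e-9)

  # a feature identical to the label is overwhelmingly significant
  r2 <- rank_features(data.frame(f = rep(0:1, each = 50)), rep(0:1, each = 50))
  expect_gt(r2$importance, 10)

  # constant feature: importance 0 with a warning
  expect_warning(r3 <- rank_features(data.frame(a = rep(1, 40), b = rnorm(40)),
                                     rep(0:1, 20)), "constant")
  expect_equal(r3$importance[r3$feature == "a"], 0)
  expect_error(rank_features(data.frame(f = rnorm(4)), c(0, 0, 0, 1)),
               "2 samples")
})

test_that("design matrices respect lags and subject/foot boundaries", {
  rows <- data.frame(subject = "S1", foot = "left", t_end = 1:5,
                     label = c(0, 1, 0, 1, 0))
  for (nm in feature_names()) rows[[nm]] <- seq_len(5) + 0.1
  d210 <- build_design_matrix(rows, "C210")
  expect_equal(dim(d210$X), c(3L, 30L))
  d0 <- build_design_matrix(rows, "C0")
  expect_equal(dim(d0$X), c(5L, 10L))
  # C21: label from the current phase, features strictly from the past
  d21 <- build_design_matrix(rows, "C21")
  expect_equal(dim(d21$X), c(3L, 20L))
  expect_equal(d21$y, rows$label[3:5])
  expect_false(any(grepl("_lag0", colnames(d21$X))))

  # two subjects of 3 phases each: one usable row per subject
  rows2 <- rows[1:3, ]; rows3 <- rows[1:3, ]; rows3$subject <- "S2"
  d2 <- build_design_matrix(rbind(rows2, rows3), "C21")
  expect_equal(nrow(d2$X), 2L)
  expect_warning(build_design_matrix(rows[1:2, ], "C210"), "empty")
})
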