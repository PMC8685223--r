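p_def <- gpd_params()

test_that("condition A debounces both directions", {
  # 10 consecutive still samples -> rest
  cnt <- 0L
  res <- NULL
  for (i in 1:10) {
    res <- check_rest_unrest(0, 0, cnt, "unrest", p_def)
    cnt <- res$counter
  }
  expect_identical(res$transition, "rest")

  # 9 still samples then one above: counter resets, no transition
  cnt <- 0L
  for (i in 1:9) cnt <- check_rest_unrest(0, 0, cnt, "unrest", p_def)$counter
  res <- check_rest_unrest(1.0, 0, cnt, "unrest", p_def)
  expect_true(is.na(res$transition))
  expect_identical(res$counter, 0L)

  # constant 1.0 m/s^2 acceleration norm for 10 samples -> unrest
  cnt <- 0L
  for (i in 1:10) {
    res <- check_rest_unrest(1.0, 0, cnt, "rest", p_def)
    cnt <- res$counter
  }
  expect_identical(res$transition, "unrest")
})

test_that("condition B fires on pitch maxima and roll/acceleration pairs", {
  fs <- 200; t <- (0:399) / fs
  deg <- pi / 180
  # pitch rises to 5 deg at t=1.0 then falls
  pitch <- 5 * deg * exp(-((t - 1)^2) / 0.02)
  ev <- check_motion_start(pitch, numeric(length(t)), numeric(length(t)), t,
                           p_def)
  expect_equal(ev$rule, "pitch_max")
  expect_equal(ev$t_start, 1.0, tolerance = 3 / fs)

  # peak of only 0.5 deg: below phi_p, no start
  expect_null(check_motion_start(0.1 * pitch, numeric(length(t)),
                                 numeric(length(t)), t, p_def))

  # roll peak at 1.0 s + filtered-acc peak (2.5 m/s^2) at 1.2 s -> start
  roll <- 3 * deg * exp(-((t - 1)^2) / 0.02)
  facc <- 2.5 * exp(-((t - 1.2)^2) / 0.02)
  ev2 <- check_motion_start(numeric(length(t)), roll, facc, t, p_def)
  expect_equal(ev2$rule, "roll_acc_corr")
  expect_equal(ev2$t_start, 1.2, tolerance = 3 / fs)
  # at 1.3 s the displacement exceeds delta = 0.25 s -> none
  facc2 <- 2.5 * exp(-((t - 1.3)^2) / 0.02)
  expect_null(check_motion_start(numeric(length(t)), roll, facc2, t, p_def))
  # and an acc peak below a_s = 2 never pairs
  expect_null(check_motion_start(numeric(length(t)), roll, 0.5 * facc, t,
                                 p_def))
})

test_that("conditions D1/D2 and the t_mot guard end a motion phase", {
  fs <- 200; n <- 60L
  t <- (0:(n - 1)) / fs
  jerk <- rep(10, n); jerk[50L] <- 30          # spike 3x the running max
  vx <- rep(0.01, n); vy <- rep(0.02, n)       # 10 % of their maxima
  vx[10L] <- 0.1; vy[10L] <- 0.2               # maxima early in the phase
  ev <- check_motion_end(jerk, vx, vy, numeric(n), numeric(n), t, p_def)
  expect_equal(ev$rule, "jerk_velocity")
  expect_equal(ev$index, 50L)

  # same spike before t0 + t_mot goes undetected
  jerk2 <- rep(10, n); jerk2[11L] <- 30        # t = 0.05 s < t_mot
  expect_null(check_motion_end(jerk2, vx, vy, numeric(n), numeric(n), t,
                               p_def))
})

test_that("condition E ends the phase on a qualified pitch minimum", {
  fs <- 200
  deg <- pi / 180
  t <- (0:199) / fs
  # rise to 20 deg then fall to -8 deg minimum at 0.7 s then recover
  pitch <- 20 * deg * exp(-((t - 0.25)^2) / 0.005) -
    8 * deg * exp(-((t - 0.7)^2) / 0.005)
  roll <- rep(2 * deg, length(t))
  ev <- check_motion_end(rep(1, length(t)), numeric(length(t)),
                         numeric(length(t)), pitch, roll, t, p_def)
  expect_equal(ev$rule, "pitch_min")
  expect_equal(ev$t_end, 0.7, tolerance = 3 / fs)
  # |phi_roll| >= phi_r blocks E
  expect_null(check_motion_end(rep(1, length(t)), numeric(length(t)),
                               numeric(length(t)), pitch,
                               rep(6 * deg, length(t)), t, p_def))
  # a min of -18 deg violates |phi| < kappa * 20 deg = 16 deg
  pitch2 <- 20 * deg * exp(-((t - 0.25)^2) / 0.005) -
    18 * deg * exp(-((t - 0.7)^2) / 0.005)
  expect_null(check_motion_end(rep(1, length(t)), numeric(length(t)),
                               numeric(length(t)), pitch2, roll, t, p_def))
})

test_that("conditions F, G, H reactivate the search state Z", {
  fs <- 200
  deg <- pi / 180
  n <- 100L
  t <- (0:(n - 1)) / fs
  still <- rep(0.001 * deg, n) # ~0.2 deg/s rate? constant -> zero rate
  # F: constant angles => zero angular rates < p1
  ev <- check_z_reactivation(still, still, rep(9.81, n) + seq_len(n) * 10,
                             t, t_end_motion = 0, fs = fs, params = p_def)
  expect_equal(ev$rule, "F")
  # reactivation needs t_x + n_r samples
  expect_gte(ev$t, 0 + p_def$t_x + (p_def$n_r - 1) / fs)

  # G: acceleration-norm variance 0.5 < p2 while angles sweep fast
  sweep_ang <- seq(0, 2, length.out = n) # huge rates, F blocked
  set.seed(1)
  acc_n <- 9.81 + rnorm(n, 0, sqrt(0.5) * 0.9)
  ev2 <- check_z_reactivation(sweep_ang, sweep_ang, acc_n, t, 0, fs, p_def)
  expect_equal(ev2$rule, "G")

  # H: a pitch local maximum of 20 deg > phi_thres fires immediately
  pitch <- 20 * deg * exp(-((t - 0.3)^2) / 0.003)
  ev3 <- check_z_reactivation(pitch, sweep_ang, seq_len(n) * 10, t, 0, fs,
                              p_def)
  expect_equal(ev3$rule, "H")
  expect_lte(abs(ev3$t - 0.3), 3 / fs)
})

test_that("an all-quiet series is one rest phase and short input errors", {
  s <- rest_series(5)
  ps <- segment_recording(s)
  expect_identical(ps$phases$phase, "rest")
  expect_equal(nrow(ps$motion), 0L)
  short <- imu_series(t = (0:4) / 200, acc = matrix(0, 5, 3),
                      gyro = matrix(0, 5, 3), fs = 200)
  expect_error(segment_recording(short), "too short")
})

test_that("clean synthetic gait segments one motion phase per stride", {
  sim <- simulate_recording(list(list(mode = "normal", n_steps = 10)),
                            seed = 1)
  ps <- segment_recording(sim$series)
  expect_equal(nrow(ps$motion), 10L)
  err_start <- abs(ps$motion$t_start - sim$truth$steps$toe_off)
  err_end <- abs(ps$motion$t_end - sim$truth$steps$initial_contact)
  expect_lte(stats::median(err_start), 0.060)
  expect_lte(stats::median(err_end), 0.060)
  expect_false(any(ps$motion$truncated))
})

test_that("festination keeps one unrest interval with Z reactivations", {
  sim <- simulate_recording(list(list(mode = "festination", n_steps = 5)),
                            seed = 2)
  ps <- segment_recording(sim$series)
  unrest <- ps$phases[ps$phases$phase == "unrest", ]
  # all motion phases inside a single unrest interval
  expect_equal(nrow(unrest), 1L)
  expect_gte(nrow(ps$motion), 5L)
  expect_gte(nrow(ps$z_reactivations), 4L)
  # differential: no F/G/H leaves exactly one motion phase
  ps0 <- segment_recording(sim$series, z_reactivation = FALSE)
  expect_equal(nrow(ps0$motion), 1L)
})

test_that("phase intervals tile the recording and nest motion phases", {
  sim <- simulate_recording(list(list(mode = "normal", n_steps = 4),
                                 list(mode = "festination", n_steps = 3)),
                            seed = 3)
  ps <- segment_recording(sim$series)
  ph <- ps$phases
  expect_equal(ph$t_start[1L], sim$series$t[1L])
  expect_equal(ph$t_end[nrow(ph)], sim$series$t[length(sim$series$t)])
  if (nrow(ph) > 1L)
    expect_equal(ph$t_start[-1L], ph$t_end[-nrow(ph)]) # no gaps, no overlap
  expect_true(all(diff(ph$t_end) > 0))
  # every motion phase lies inside one unrest interval
  unrest <- ph[ph$phase == "unrest", ]
  for (j in seq_len(nrow(ps$motion))) {
    inside <- unrest$t_start <= ps$motion$t_start[j] + 1e-9 &
      unrest$t_end >= ps$motion$t_end[j] - 1e-9
    expect_true(any(inside))
  }
  # Z bookkeeping: starts per unrest interval = 1 + reactivations in it
  for (k in seq_len(nrow(unrest))) {
    n_mp <- sum(ps$motion$t_start >= unrest$t_start[k] &
                  ps$motion$t_end <= unrest$t_end[k])
    n_z <- sum(ps$z_reactivations$t > unrest$t_start[k] &
                 ps$z_reactivations$t < unrest$t_end[k])
    if (n_mp > 0L) expect_equal(n_mp, 1L + n_z)
  }
})

test_that("segmentation is deterministic and causal (prefix-consistent)", {
  sim <- simulate_recording(list(list(mode = "normal", n_steps = 3)), seed = 4)
  ps1 <- segment_recording(sim$series)
  ps2 <- segment_recording(sim$series)
  expect_identical(ps1$phases, ps2$phases)
  expect_identical(ps1$motion, ps2$motion)
  expect_identical(ps1$trace, ps2$trace)

  # truncate mid-recording: the per-sample trace of the prefix run equals
  # the head of the full-run trace (no lookahead anywhere)
  n <- length(sim$series$t)
  ncut <- floor(0.6 * n)
  pre <- imu_series(sim$series$t[1:ncut], sim$series$acc[1:ncut, ],
                    sim$series$gyro[1:ncut, ], fs = sim$series$fs)
  psp <- segment_recording(pre)
  cols <- c("phase", "in_motion", "z_active", "pitch_d", "jerk", "vx", "vy")
  expect_identical(psp$trace[, cols], ps1$trace[1:ncut, cols])
})

test_that("raising the rest bounds never shrinks total rest duration", {
  sim <- simulate_recording(list(list(mode = "normal", n_steps = 5)), seed = 6)
  durs <- vapply(c(1, 1.5, 2.5), function(s) {
    rest_duration(segment_recording(
      sim$series, gpd_params(a_rest = 0.5 * s, w_rest = 0.11 * s)))
  }, numeric(1))
  expect_true(all(diff(durs) >= 0))
})
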