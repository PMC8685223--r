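# Synthetic foot-IMU gait generator with analytic ground truth.
#
# A step is built from closed-form kinematics: the foot pitch rises from
# zero to a heel-off maximum (two joined raised-cosine arcs), falls
# monotonically through a negative trough late in swing, and returns to
# zero at initial contact, where a short high-jerk vertical acceleration
# transient models the ground impact. Horizontal displacement follows a
# minimum-jerk profile with zero end velocity; gravity is added and all
# signals are rotated into the sensor frame (z up, y against the walking
# direction) before white Gaussian sensor noise is applied. The analytic
# trajectory is retained as ground truth.

#' Synthetic gait profile
#'
#' Default morphology of a clean stride: 0.6 m stride, 0.7 s swing,
#' 20 deg heel-off pitch maximum and -25 deg swing trough, 0.2 s
#' heel-off rise, 0.5 s inter-step rest gap, 5 cm foot lift, an 8 m/s^2
#' 30 ms contact transient, and white sensor noise of 0.03 m/s^2 /
#' 0.002 rad/s.
#'
#' @param stride_length m.
#' @param swing_duration s (toe-off to initial contact).
#' @param rise_duration s (heel-off pitch rise before toe-off).
#' @param rest_gap s of rest between steps.
#' @param pitch_up_deg,pitch_down_deg heel-off maximum and swing trough
#'   magnitude, deg.
#' @param foot_lift m of vertical foot excursion.
#' @param sway_acc lateral acceleration amplitude, m/s^2.
#' @param contact_amp,contact_dur vertical contact-transient amplitude
#'   (m/s^2) and duration (s).
#' @param noise_sd_acc,noise_sd_gyro sensor noise SDs (m/s^2, rad/s).
#' @param fs sampling rate, Hz.
#' @return object of class `gait_profile`.
#' @export
gait_profile <- function(stride_length = 0.6, swing_duration = 0.7,
                         rise_duration = 0.2, rest_gap = 0.5,
                         pitch_up_deg = 20, pitch_down_deg = 25,
                         foot_lift = 0.05, sway_acc = 0.3,
                         contact_amp = 8, contact_dur = 0.03,
                         noise_sd_acc = 0.03, noise_sd_gyro = 0.002,
                         fs = 200) {
  p <- list(stride_length = stride_length, swing_duration = swing_duration,
            rise_duration = rise_duration, rest_gap = rest_gap,
            pitch_up_deg = pitch_up_deg, pitch_down_deg = pitch_down_deg,
            foot_lift = foot_lift, sway_acc = sway_acc,
            contact_amp = contact_amp, contact_dur = contact_dur,
            noise_sd_acc = noise_sd_acc, noise_sd_gyro = noise_sd_gyro,
            fs = fs)
  for (nm in c("stride_length", "swing_duration", "rise_duration", "fs"))
    if (p[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  structure(p, class = "gait_profile")
}

# Mode-specific rescaling of a profile (FoG subtype morphology):
# shuffling = inadequate foot lift (pitch scale <= 0.3, short strides);
# festination = small fast steps (period <= 0.4 s); trembling and
# akinesia are handled as dedicated segment types.
.mode_profile <- function(profile, mode) {
  p <- profile
  if (mode == "shuffling") {
    p$pitch_up_deg <- profile$pitch_up_deg * 0.3
    p$pitch_down_deg <- profile$pitch_down_deg * 0.3
    p$stride_length <- profile$stride_length * 0.4
    p$swing_duration <- profile$swing_duration * 0.8
    p$foot_lift <- profile$foot_lift * 0.3
  } else if (mode == "festination") {
    p$pitch_up_deg <- profile$pitch_up_deg * 0.4
    p$pitch_down_deg <- profile$pitch_down_deg * 0.4
    p$stride_length <- 0.12
    p$swing_duration <- 0.2
    p$rise_duration <- 0.14
    p$rest_gap <- 0.04 # shorter than the n_r debounce: no rest between steps
    p$foot_lift <- 0.02
    p$contact_amp <- 6
  }
  p
}

# Pitch trajectory (rad) and its rate over local time t for one step:
# raised-cosine rise 0 -> A_up over [0, Tr], fall A_up -> -A_dn over
# [Tr, Tr + 0.8 Ts], recovery -A_dn -> 0 over [Tr + 0.8 Ts, Tr + Ts].
.step_pitch <- function(t, Tr, Ts, A_up, A_dn) {
  th <- numeric(length(t)); rate <- numeric(length(t))
  T2 <- 0.8 * Ts; T3 <- 0.2 * Ts
  i1 <- t >= 0 & t < Tr
  u <- t[i1] / Tr
  th[i1] <- A_up * 0.5 * (1 - cos(pi * u))
  rate[i1] <- A_up * 0.5 * pi * sin(pi * u) / Tr
  i2 <- t >= Tr & t < Tr + T2
  u <- (t[i2] - Tr) / T2
  th[i2] <- -A_dn + (A_up + A_dn) * 0.5 * (1 + cos(pi * u))
  rate[i2] <- -(A_up + A_dn) * 0.5 * pi * sin(pi * u) / T2
  i3 <- t >= Tr + T2 & t < Tr + Ts
  u <- (t[i3] - Tr - T2) / T3
  th[i3] <- -A_dn * 0.5 * (1 + cos(pi * u))
  rate[i3] <- A_dn * 0.5 * pi * sin(pi * u) / T3
  list(pitch = th, rate = rate)
}

# Minimum-jerk displacement profile and derivatives on u in [0,1].
.minjerk <- function(u) {
  list(p = 10 * u^3 - 15 * u^4 + 6 * u^5,
       v = 30 * u^2 - 60 * u^3 + 30 * u^4,
       a = 60 * u - 180 * u^2 + 120 * u^3)
}

#' Simulate one step (or one FoG segment building block)
#'
#' Generates the sensor-frame 6-channel signals of a single step of the
#' requested mode together with its analytic ground truth. Local time
#' starts at 0; the caller offsets and concatenates.
#'
#' @param profile a [gait_profile()].
#' @param mode `"normal"`, `"shuffling"`, or `"festination"` (trembling
#'   and akinesia segments are generated by [simulate_recording()]).
#' @param yaw_start,yaw_end heading at segment start/end, rad (a turning
#'   step sweeps the difference across the swing).
#' @param noise logical; add sensor noise (uses the current RNG state).
#' @return list with `t` (local), `acc`, `gyro` (n x 3, sensor frame),
#'   `truth` (toe_off, initial_contact, stride_length, swing_duration,
#'   pitch_max), analytic `pos` (n x 3 global position) and `pitch`,
#'   and `duration`.
#' @export
simulate_step <- function(profile, mode = "normal", yaw_start = 0,
                          yaw_end = yaw_start, noise = TRUE) {
  p <- .mode_profile(profile, mode)
  fs <- p$fs; dt <- 1 / fs
  Tr <- p$rise_duration; Ts <- p$swing_duration
  if (Ts <= p$contact_dur)
    stop("inconsistent profile: swing shorter than contact transient",
         call. = FALSE)
  dur <- Tr + Ts + p$contact_dur + p$rest_gap
  t <- seq(0, dur - dt / 2, by = dt)
  n <- length(t)
  A_up <- p$pitch_up_deg * pi / 180
  A_dn <- p$pitch_down_deg * pi / 180
  pp <- .step_pitch(t, Tr, Ts, A_up, A_dn)

  # path-frame linear kinematics during swing (x lateral, y backward)
  u <- pmin(pmax((t - Tr) / Ts, 0), 1)
  in_swing <- t >= Tr & t < Tr + Ts
  mj <- .minjerk(u)
  a_path <- matrix(0, n, 3L)
  pos_path <- matrix(0, n, 3L)
  a_path[in_swing, 2L] <- -p$stride_length * mj$a[in_swing] / Ts^2
  pos_path[, 2L] <- -p$stride_length * mj$p
  a_path[in_swing, 1L] <- p$sway_acc * sin(2 * pi * u[in_swing])
  a_path[in_swing, 3L] <- -p$foot_lift * (pi / Ts)^2 * sin(pi * u[in_swing])
  pos_path[, 3L] <- p$foot_lift * sin(pi * pmin(u, 1))
  # contact transient: vertical half-sine spike right after initial contact
  t_ic <- Tr + Ts
  in_ct <- t >= t_ic & t < t_ic + p$contact_dur
  a_path[in_ct, 3L] <- a_path[in_ct, 3L] +
    p$contact_amp * sin(pi * (t[in_ct] - t_ic) / p$contact_dur)

  # heading ramp across the swing (turning steps)
  dpsi <- yaw_end - yaw_start
  psi <- yaw_start + dpsi * mj$p
  psi_rate <- numeric(n)
  psi_rate[in_swing] <- dpsi * mj$v[in_swing] / Ts

  acc <- matrix(0, n, 3L); gyro <- matrix(0, n, 3L)
  pos <- matrix(0, n, 3L)
  g <- c(0, 0, 9.81)
  for (i in seq_len(n)) {
    cz <- cos(psi[i]); sz <- sin(psi[i])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3L, byrow = TRUE)
    cx <- cos(pp$pitch[i]); sx <- sin(pp$pitch[i])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, byrow = TRUE)
    R <- Rz %*% Rx # sensor -> global
    a_glob <- Rz %*% a_path[i, ] # path frame rotates with heading
    pos[i, ] <- Rz %*% pos_path[i, ]
    acc[i, ] <- t(R) %*% (a_glob + g)
    w_glob <- c(0, 0, psi_rate[i]) + Rz %*% c(pp$rate[i], 0, 0)
    gyro[i, ] <- t(R) %*% w_glob
  }
  if (noise) {
    acc <- acc + matrix(stats::rnorm(3L * n, 0, p$noise_sd_acc), n, 3L)
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, p$noise_sd_gyro), n, 3L)
  }
  list(t = t, acc = acc, gyro = gyro,
       truth = list(toe_off = Tr, initial_contact = t_ic,
                    stride_length = p$stride_length, swing_duration = Ts,
                    pitch_max = A_up),
       pos = pos, pitch = pp$pitch, duration = dur)
}

# Trembling segment: shank oscillation at f_hz lifting the heel between
# 0 and amp_deg; small linear acceleration wobble, no displacement.
.simulate_tremble <- function(profile, duration, f_hz = 5, amp_deg = 3,
                              noise = TRUE) {
  fs <- profile$fs; dt <- 1 / fs
  t <- seq(0, duration - dt / 2, by = dt)
  n <- length(t)
  A <- amp_deg * pi / 180
  env <- pmin(t / 0.2, 1) * pmin((duration - t) / 0.2, 1) # soft on/off
  th <- A * 0.5 * (1 - cos(2 * pi * f_hz * t)) * env
  rate <- c(0, diff(th)) / dt
  acc <- matrix(0, n, 3L); gyro <- matrix(0, n, 3L)
  g <- c(0, 0, 9.81)
  # heel bounce has a vertical component, so the acceleration norm itself
  # oscillates at the trembling frequency (not its double)
  a_lin <- 0.4 * sin(2 * pi * f_hz * t) * env # m/s^2
  for (i in seq_len(n)) {
    cx <- cos(th[i]); sx <- sin(th[i])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, byrow = TRUE)
    acc[i, ] <- t(Rx) %*% (c(0, 0.5 * a_lin[i], a_lin[i]) + g)
    gyro[i, ] <- c(rate[i], 0, 0)
  }
  if (noise) {
    acc <- acc + matrix(stats::rnorm(3L * n, 0, profile$noise_sd_acc), n, 3L)
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, profile$noise_sd_gyro), n, 3L)
  }
  list(t = t, acc = acc, gyro = gyro, duration = t[n] + dt)
}

.simulate_rest <- function(profile, duration, noise = TRUE) {
  fs <- profile$fs; dt <- 1 / fs
  t <- seq(0, duration - dt / 2, by = dt)
  n <- length(t)
  acc <- matrix(rep(c(0, 0, 9.81), each = n), n, 3L)
  gyro <- matrix(0, n, 3L)
  if (noise) {
    acc <- acc + matrix(stats::rnorm(3L * n, 0, profile$noise_sd_acc), n, 3L)
    gyro <- gyro + matrix(stats::rnorm(3L * n, 0, profile$noise_sd_gyro), n, 3L)
  }
  list(t = t, acc = acc, gyro = gyro, duration = t[n] + dt)
}

#' Simulate a full recording from a scenario list
#'
#' Concatenates rest, walking, turning and FoG segments into one
#' recording with continuous heading, ground-truth step events, true
#' episode intervals per FoG segment, and two simulated expert raters
#' whose episode boundaries are jittered by `rater_jitter_sd`.
#'
#' Scenario entries are lists with `mode` in `"rest"`, `"normal"`,
#' `"shuffling"`, `"festination"`, `"trembling"`, `"akinesia"`, plus
#' `n_steps` (step modes), `duration` (rest/trembling/akinesia),
#' `turn_deg` (total heading change across the segment's steps), and
#' optional trembling `f_hz`/`amp_deg`.
#'
#' @param scenarios list of scenario entries, in temporal order.
#' @param profile a [gait_profile()].
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param lead_in_rest s of rest prepended for filter convergence and
#'   offset estimation.
#' @param rater_jitter_sd SD of the simulated raters' episode-boundary
#'   jitter, s.
#' @param noise logical; disable for noise-free signals.
#' @param foot,subject_id metadata for the returned series.
#' @return list with `series` (an [imu_series()]), `truth` (data.frame
#'   `steps` with true toe-off/initial-contact times, stride length,
#'   swing duration and mode; data.frame `episodes`), `raters` (list of
#'   two jittered annotation data.frames), and `segments`.
#' @export
simulate_recording <- function(scenarios, profile = gait_profile(), seed = 1L,
                               lead_in_rest = 2, rater_jitter_sd = 0.1,
                               noise = TRUE, foot = "left",
                               subject_id = "S0") {
  set.seed(as.integer(seed))
  fs <- profile$fs
  acc <- list(); gyro <- list()
  steps <- list(); episodes <- list(); segments <- list()
  t_off <- 0; yaw <- 0
  add_seg <- function(seg) {
    acc[[length(acc) + 1L]] <<- seg$acc
    gyro[[length(gyro) + 1L]] <<- seg$gyro
    t_off <<- t_off + seg$duration
  }
  if (lead_in_rest > 0)
    add_seg(.simulate_rest(profile, lead_in_rest, noise))
  for (sc in scenarios) {
    mode <- sc$mode
    seg_start <- t_off
    if (mode %in% c("rest", "akinesia")) {
      add_seg(.simulate_rest(profile, sc$duration, noise))
    } else if (mode == "trembling") {
      f_hz <- if (is.null(sc$f_hz)) 5 else sc$f_hz
      amp <- if (is.null(sc$amp_deg)) 3 else sc$amp_deg
      add_seg(.simulate_tremble(profile, sc$duration, f_hz, amp, noise))
    } else {
      n_steps <- sc$n_steps
      turn <- if (is.null(sc$turn_deg)) 0 else sc$turn_deg * pi / 180
      dpsi <- turn / n_steps
      for (k in seq_len(n_steps)) {
        st <- simulate_step(profile, mode, yaw_start = yaw,
                            yaw_end = yaw + dpsi, noise = noise)
        steps[[length(steps) + 1L]] <- data.frame(
          mode = mode,
          toe_off = t_off + st$truth$toe_off,
          initial_contact = t_off + st$truth$initial_contact,
          stride_length = st$truth$stride_length,
          swing_duration = st$truth$swing_duration,
          turned = dpsi != 0)
        yaw <- yaw + dpsi
        add_seg(st)
      }
    }
    segments[[length(segments) + 1L]] <- data.frame(
      mode = mode, t_start = seg_start, t_end = t_off)
    if (mode %in% c("shuffling", "festination", "trembling", "akinesia"))
      episodes[[length(episodes) + 1L]] <- data.frame(
        start = seg_start, end = t_off, subtype = mode)
  }
  acc <- do.call(rbind, acc); gyro <- do.call(rbind, gyro)
  n <- nrow(acc)
  series <- imu_series(t = (seq_len(n) - 1) / fs, acc = acc, gyro = gyro,
                       fs = fs, foot = foot, subject_id = subject_id)
  episodes_df <- if (length(episodes)) do.call(rbind, episodes)
  else data.frame(start = numeric(0), end = numeric(0),
                  subtype = character(0))
  t_max <- (n - 1) / fs
  jitter_rater <- function(rater) {
    if (nrow(episodes_df) == 0L)
      return(cbind(episodes_df[0, ], rater = character(0)))
    e <- episodes_df
    e$start <- pmax(0, e$start + stats::rnorm(nrow(e), 0, rater_jitter_sd))
    e$end <- pmin(t_max, e$end + stats::rnorm(nrow(e), 0, rater_jitter_sd))
    bad <- e$end <= e$start
    e$end[bad] <- e$start[bad] + 0.1
    e$rater <- rater
    e[order(e$start), ]
  }
  raters <- list(expert1 = jitter_rater("expert1"),
                 expert2 = jitter_rater("expert2"))
  list(series = series,
       truth = list(
         steps = if (length(steps)) do.call(rbind, steps)
         else data.frame(),
         episodes = episodes_df),
       raters = raters,
       segments = do.call(rbind, segments))
}

#' Simulate a feature-level cohort for classifier evaluation
#'
#' Draws, for each pseudo-subject and foot, a sequence of motion-phase
#' feature rows with binary FoG labels. Labels follow a persistent
#' two-state Markov chain (FoG comes in episodes) with per-subject
#' prevalence scattered around `fog_prevalence`; FoG rows shift the
#' five strongest gait features (maximum velocity, step duration,
#' stride length, maximum and minimum pitch) by `effect_size` within-
#' subject standard deviations in their clinically expected directions.
#' Between-subject variation perturbs every feature's baseline mean.
#'
#' @param n_subjects number of pseudo-subjects (>= 2).
#' @param fog_prevalence target fraction of FoG phases in (0, 1).
#' @param effect_size standardised FoG effect d on the affected
#'   features.
#' @param seed integer seed.
#' @param phases_per_foot average motion phases per foot.
#' @param persistence label autocorrelation of the episode chain.
#' @param subject_sd between-subject SD of feature baselines, in units
#'   of the within-subject SD.
#' @return data.frame with `subject`, `foot`, `t_end`, `label`, and the
#'   10 features, ready for [build_design_matrix()] /
#'   [lopo_cross_validate()].
#' @export
simulate_cohort <- function(n_subjects = 16L, fog_prevalence = 0.65,
                            effect_size = 2, seed = 1L,
                            phases_per_foot = 80L, persistence = 0.8,
                            subject_sd = 0.3) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  if (fog_prevalence <= 0 || fog_prevalence >= 1)
    stop("fog_prevalence must be in (0, 1)", call. = FALSE)
  set.seed(as.integer(seed))
  base_mean <- c(max_acc_norm = 8, max_pitch = 0.35, min_pitch = -0.44,
                 stride_length = 0.6, max_velocity = 1.6,
                 turning_angle = 0, turned_flag = 0.2, max_turn_rate = 1.5,
                 mean_turn_rate = 0.6, step_duration = 0.7)
  base_sd <- c(max_acc_norm = 2, max_pitch = 0.08, min_pitch = 0.1,
               stride_length = 0.15, max_velocity = 0.4,
               turning_angle = 0.3, turned_flag = 0.4, max_turn_rate = 0.5,
               mean_turn_rate = 0.2, step_duration = 0.1)
  # clinically expected FoG directions on the five strongest features
  effect_dir <- c(max_acc_norm = 0, max_pitch = -1, min_pitch = +1,
                  stride_length = -1, max_velocity = -1, turning_angle = 0,
                  turned_flag = 0, max_turn_rate = 0, mean_turn_rate = 0,
                  step_duration = -1)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("S%02d", s)
    mu_s <- base_mean + stats::rnorm(10L, 0, subject_sd * base_sd)
    prev_s <- min(0.9, max(0.1, fog_prevalence + stats::rnorm(1, 0, 0.05)))
    p_enter <- (1 - persistence) * prev_s
    p_stay <- persistence + p_enter
    for (ft in c("left", "right")) {
      n_ph <- max(10L, round(phases_per_foot * stats::runif(1, 0.8, 1.2)))
      lab <- integer(n_ph)
      lab[1L] <- stats::rbinom(1L, 1L, prev_s)
      for (i in 2:n_ph)
        lab[i] <- stats::rbinom(1L, 1L,
                                if (lab[i - 1L] == 1L) p_stay else p_enter)
      X <- matrix(stats::rnorm(n_ph * 10L), n_ph, 10L)
      X <- sweep(X, 2L, base_sd, `*`)
      X <- sweep(X, 2L, mu_s, `+`)
      X <- X + outer(lab, effect_size * effect_dir * base_sd)
      colnames(X) <- names(base_mean)
      X[, "turned_flag"] <- as.numeric(X[, "turned_flag"] > 0.5)
      X[, "step_duration"] <- pmax(X[, "step_duration"], 0.1)
      X[, "stride_length"] <- pmax(X[, "stride_length"], 0)
      X[, "max_turn_rate"] <- abs(X[, "max_turn_rate"])
      X[, "mean_turn_rate"] <- abs(X[, "mean_turn_rate"])
      rows[[paste(subj, ft)]] <- cbind(
        data.frame(subject = subj, foot = ft,
                   t_end = cumsum(X[, "step_duration"] +
                                    stats::runif(n_ph, 0.3, 0.8)),
                   label = lab),
        as.data.frame(X))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
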