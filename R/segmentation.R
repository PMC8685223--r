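# Rest/unrest/motion state machine with reactivation state Z.
#
# Conventions used throughout:
#  - condition A: n_r-debounced threshold test on the detrended global
#    acceleration and angular-rate norms (both directions debounced);
#  - condition B: motion start on a pitch local maximum > phi_p, or on a
#    roll maximum paired (within delta) with a filtered-acceleration-norm
#    maximum > a_s;
#  - conditions D1/D2: motion end on a jerk spike exceeding alpha times
#    the running maximum registered before the current sample while both
#    horizontal velocities are below beta times their running maxima;
#  - condition E: motion end on a pitch local minimum with small roll and
#    |pitch| < kappa * pitch_max;
#  - conditions F/G/H: reactivation of the search state Z inside an
#    ongoing unrest phase (angular-rate stillness, low acceleration-norm
#    variance, or a tall pitch maximum).
# A local extremum is a sign change of the first difference confirmed by
# one sample; ties break toward the earlier sample.

.local_extrema <- function(x, type = c("max", "min")) {
  type <- match.arg(type)
  n <- length(x)
  if (n < 3L) return(integer(0))
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[3:n] - x[2:(n - 1)]
  idx <- if (type == "max") which(d1 > 0 & d2 <= 0) else which(d1 < 0 & d2 >= 0)
  idx + 1L
}

#' Rest/unrest transition check (condition A)
#'
#' Single-sample stepper for the debounced rest/unrest transition: a
#' transition fires after `n_r` consecutive samples on the other side of
#' the thresholds.
#'
#' @param a_dg_norm,w_dg_norm detrended global acceleration (m/s^2) and
#'   angular-rate (rad/s) norms of the current sample.
#' @param counter consecutive-sample counter carried between calls
#'   (start at 0).
#' @param phase current phase, `"rest"` or `"unrest"`.
#' @param params a [gpd_params()].
#' @return list with `transition` (`"rest"`, `"unrest"`, or `NA`) and
#'   the updated `counter`.
#' @export
check_rest_unrest <- function(a_dg_norm, w_dg_norm, counter, phase, params) {
  still <- (a_dg_norm < params$a_rest) && (w_dg_norm < params$w_rest)
  hit <- if (phase == "rest") !still else still
  counter <- if (hit) counter + 1L else 0L
  if (counter >= params$n_r) {
    list(transition = if (phase == "rest") "unrest" else "rest", counter = 0L)
  } else {
    list(transition = NA_character_, counter = counter)
  }
}

#' Motion-start check (condition B)
#'
#' Reference (vector-scan) implementation of the motion-start rule: the
#' earliest of (i) a pitch local maximum exceeding `phi_p`, or (ii) a
#' roll local maximum and a local maximum of the `n_a`-sample
#' moving-average acceleration norm exceeding `a_s` within `delta`
#' seconds of each other (start at the later of the two peaks).
#'
#' @param pitch_d,roll_d detrended pitch/roll angle histories, radians.
#' @param facc_norm moving-average-filtered detrended acceleration norm
#'   history, m/s^2 (same length).
#' @param t sample times, s.
#' @param params a [gpd_params()].
#' @return `NULL`, or a list with `t_start`, `index` (peak sample) and
#'   `rule` (`"pitch_max"` or `"roll_acc_corr"`).
#' @export
check_motion_start <- function(pitch_d, roll_d, facc_norm, t, params) {
  phi_p <- params$phi_p * pi / 180
  pk <- .local_extrema(pitch_d, "max")
  pk <- pk[pitch_d[pk] > phi_p]
  cand <- if (length(pk)) list(index = pk[1L], rule = "pitch_max") else NULL
  rmax <- .local_extrema(roll_d, "max")
  amax <- .local_extrema(facc_norm, "max")
  amax <- amax[facc_norm[amax] > params$a_s]
  if (length(rmax) && length(amax)) {
    best <- NULL
    for (i in rmax) for (j in amax) {
      if (abs(t[i] - t[j]) <= params$delta) {
        k <- max(i, j) # start at the later peak; decided one sample after it
        if (is.null(best) || k < best) best <- k
      }
    }
    if (!is.null(best) && (is.null(cand) || best < cand$index))
      cand <- list(index = best, rule = "roll_acc_corr")
  }
  if (is.null(cand)) return(NULL)
  list(t_start = t[cand$index], index = cand$index, rule = cand$rule)
}

#' Motion-end check (conditions D1, D2, E)
#'
#' Reference implementation scanning one motion phase. End conditions
#' are evaluated only for `t > t0 + t_mot`. D1 compares the current jerk
#' against `alpha` times the running maximum registered before the
#' current sample; D2 requires both horizontal velocity magnitudes below
#' `beta` times their running maxima (current sample included). E fires
#' on a pitch local minimum with `|roll| < phi_r` and
#' `|pitch| < kappa * max(pitch)` over the phase so far.
#'
#' @param jerk jerk-norm history from motion start, m/s^3.
#' @param vx,vy horizontal strap-down velocity histories, m/s.
#' @param pitch_d,roll_d detrended pitch/roll histories, radians.
#' @param t sample times, s; `t[1]` is the motion start `t0`.
#' @param params a [gpd_params()].
#' @return `NULL`, or a list with `t_end`, `index` and `rule`
#'   (`"jerk_velocity"` or `"pitch_min"`).
#' @export
check_motion_end <- function(jerk, vx, vy, pitch_d, roll_d, t, params) {
  phi_r <- params$phi_r * pi / 180
  t0 <- t[1L]
  n <- length(t)
  max_jerk <- jerk[1L]
  vmax_x <- abs(vx[1L]); vmax_y <- abs(vy[1L])
  pitch_max <- pitch_d[1L]
  for (i in seq_len(n)[-1L]) {
    vmax_x <- max(vmax_x, abs(vx[i])); vmax_y <- max(vmax_y, abs(vy[i]))
    if (t[i] > t0 + params$t_mot) {
      d1 <- max_jerk > 0 && jerk[i] > params$alpha * max_jerk
      d2 <- abs(vx[i]) < params$beta * vmax_x && abs(vy[i]) < params$beta * vmax_y
      if (d1 && d2)
        return(list(t_end = t[i], index = i, rule = "jerk_velocity"))
      if (i >= 3L) {
        is_min <- (pitch_d[i - 1L] - pitch_d[i - 2L]) < 0 &&
          (pitch_d[i] - pitch_d[i - 1L]) >= 0
        if (is_min && abs(roll_d[i - 1L]) < phi_r &&
            abs(pitch_d[i - 1L]) < params$kappa * pitch_max)
          return(list(t_end = t[i - 1L], index = i - 1L, rule = "pitch_min"))
      }
    }
    max_jerk <- max(max_jerk, jerk[i])
    pitch_max <- max(pitch_max, pitch_d[i])
  }
  NULL
}

#' Z-reactivation check (conditions F, G, H)
#'
#' Reference implementation scanning the samples after a completed
#' motion phase. Checking starts once `t_x` seconds have elapsed since
#' the motion end with no rest phase. Z reactivates after `n_r`
#' consecutive samples satisfying F (pitch and roll angular rates below
#' `p1`, or the angles themselves when `f_on_angles`) or G (sliding
#' `n_r`-sample variance of the raw acceleration norm below `p2`), or
#' immediately on H (pitch local maximum above `phi_thres`).
#'
#' @param pitch_d,roll_d detrended pitch/roll histories, radians.
#' @param acc_norm raw sensor acceleration-norm history, m/s^2.
#' @param t sample times, s.
#' @param t_end_motion end time of the preceding motion phase, s.
#' @param fs sampling rate, Hz.
#' @param params a [gpd_params()].
#' @return `NULL`, or a list with `t`, `index` and `rule`
#'   (`"F"`, `"G"`, or `"H"`).
#' @export
check_z_reactivation <- function(pitch_d, roll_d, acc_norm, t, t_end_motion,
                                 fs, params) {
  dt <- 1 / fs
  p1 <- params$p1 * pi / 180 # deg/s -> rad/s (or deg -> rad on angles)
  n <- length(t)
  cnt_f <- 0L; cnt_g <- 0L
  for (i in seq_len(n)) {
    if (t[i] <= t_end_motion + params$t_x) next
    if (params$f_on_angles) {
      f_ok <- abs(pitch_d[i]) < p1 && abs(roll_d[i]) < p1
    } else {
      f_ok <- i >= 2L &&
        abs(pitch_d[i] - pitch_d[i - 1L]) / dt < p1 &&
        abs(roll_d[i] - roll_d[i - 1L]) / dt < p1
    }
    cnt_f <- if (f_ok) cnt_f + 1L else 0L
    g_ok <- i >= params$n_r &&
      stats::var(acc_norm[(i - params$n_r + 1L):i]) < params$p2
    cnt_g <- if (g_ok) cnt_g + 1L else 0L
    h_ok <- i >= 3L &&
      (pitch_d[i - 1L] - pitch_d[i - 2L]) > 0 &&
      (pitch_d[i] - pitch_d[i - 1L]) <= 0 &&
      pitch_d[i - 1L] > params$phi_thres * pi / 180
    if (h_ok) return(list(t = t[i], index = i, rule = "H"))
    if (cnt_f >= params$n_r) return(list(t = t[i], index = i, rule = "F"))
    if (cnt_g >= params$n_r) return(list(t = t[i], index = i, rule = "G"))
  }
  NULL
}

#' Segment a recording into rest, unrest and motion phases
#'
#' Runs the full causal, single-pass pipeline: complementary orientation
#' filtering, global-frame transformation with rest-gated offset
#' estimation, jerk monitoring, strap-down velocity integration inside
#' motion phases, and the rest/unrest/motion state machine with
#' reactivation state Z.
#'
#' @param series an [imu_series()].
#' @param params a [gpd_params()].
#' @param z_reactivation logical; disable to suppress conditions F/G/H
#'   (at most one motion phase per unrest interval).
#' @param tau_acc orientation-filter time constant, s
#'   (see [update_orientation()]).
#' @param g gravity magnitude, m/s^2.
#' @param keep_trace logical; keep the per-sample kinematic trace in the
#'   result (required for feature extraction).
#' @return object of class `phase_sequence`: a list with
#'   \describe{
#'     \item{phases}{data.frame of `phase` (`"rest"`/`"unrest"`),
#'       `t_start`, `t_end` tiling the recording,}
#'     \item{motion}{data.frame of motion phases with `t_start`,
#'       `t_end`, `start_rule`, `end_rule`, `truncated`,}
#'     \item{z_reactivations}{data.frame of reactivation events
#'       (`t`, `rule`),}
#'     \item{trace}{per-sample kinematics and state trace (if kept),}
#'     \item{fs, params}{bookkeeping.}
#'   }
#' @export
segment_recording <- function(series, params = gpd_params(),
                              z_reactivation = TRUE, tau_acc = 0.5,
                              g = 9.81, keep_trace = TRUE) {
  stopifnot(inherits(series, "imu_series"))
  n <- length(series$t)
  if (n < params$n_r)
    stop("series too short: need at least n_r samples", call. = FALSE)
  dt <- 1 / series$fs
  tt <- series$t

  phi_p <- params$phi_p * pi / 180
  phi_r <- params$phi_r * pi / 180
  phi_thres <- params$phi_thres * pi / 180
  p1 <- params$p1 * pi / 180
  kappa <- params$kappa

  # per-sample trace
  tr <- matrix(0, n, 16L)
  colnames(tr) <- c("phase", "in_motion", "z_active", "pitch_d", "roll_d",
                    "yaw_d", "adgx", "adgy", "adgz", "jerk", "vx", "vy",
                    "a_norm", "w_norm", "facc", "raw_norm")

  q <- quat_from_accel(series$acc[1, ])
  off <- rest_offsets(window = params$n_d)
  prev_adg <- NULL

  phase <- "rest"; phase_start <- tt[1L]
  cnt_a <- 0L
  in_motion <- FALSE; z_active <- FALSE
  t0 <- NA_real_; i0 <- NA_integer_; start_rule <- NA_character_
  max_jerk_prev <- 0; pitch_max <- -Inf
  v <- c(0, 0, 0); vmax_x <- 0; vmax_y <- 0
  motion_end_t <- NA_real_; rest_since_end <- TRUE
  cnt_f <- 0L; cnt_g <- 0L
  last_roll_max_t <- NA_real_; last_facc_max_t <- NA_real_

  ma_buf <- numeric(0)     # moving-average buffer for facc
  raw_buf <- numeric(0)    # raw acc norm buffer for condition G

  phases <- list(); motion <- list(); zreact <- list()

  close_motion <- function(t_end, rule, truncated = FALSE) {
    motion[[length(motion) + 1L]] <<- list(
      t_start = t0, t_end = t_end, start_rule = start_rule,
      end_rule = rule, truncated = truncated)
    in_motion <<- FALSE
    z_active <<- FALSE
    motion_end_t <<- t_end
    rest_since_end <<- FALSE
    cnt_f <<- 0L; cnt_g <<- 0L
    last_roll_max_t <<- NA_real_; last_facc_max_t <<- NA_real_
  }

  for (i in seq_len(n)) {
    if (i > 1L) {
      # midpoint angular rate: second-order strap-down integration
      gyro_mid <- 0.5 * (series$gyro[i - 1L, ] + series$gyro[i, ])
      q <- update_orientation(q, series$acc[i, ], gyro_mid, dt, tau_acc)
    }
    k <- transform_and_detrend(series$acc[i, ], series$gyro[i, ], q, off, g)
    jerk <- if (is.null(prev_adg)) 0 else compute_jerk(prev_adg, k$a_dg, dt)
    na_ <- sqrt(sum(k$a_dg^2)); nw_ <- sqrt(sum(k$w_dg^2))
    raw_norm <- sqrt(sum(series$acc[i, ]^2))

    ma_buf <- c(ma_buf, na_)
    if (length(ma_buf) > params$n_a) ma_buf <- ma_buf[-1L]
    facc <- mean(ma_buf)
    raw_buf <- c(raw_buf, raw_norm)
    if (length(raw_buf) > params$n_r) raw_buf <- raw_buf[-1L]

    pitch <- k$euler_d[["pitch"]]; roll <- k$euler_d[["roll"]]
    yaw <- k$euler_d[["yaw"]]

    # histories for extremum detection (previous two samples from trace)
    p1v <- if (i >= 2L) tr[i - 1L, "pitch_d"] else NA_real_
    p2v <- if (i >= 3L) tr[i - 2L, "pitch_d"] else NA_real_
    r1v <- if (i >= 2L) tr[i - 1L, "roll_d"] else NA_real_
    r2v <- if (i >= 3L) tr[i - 2L, "roll_d"] else NA_real_
    f1v <- if (i >= 2L) tr[i - 1L, "facc"] else NA_real_
    f2v <- if (i >= 3L) tr[i - 2L, "facc"] else NA_real_
    pitch_peak <- i >= 3L && (p1v - p2v) > 0 && (pitch - p1v) <= 0
    pitch_trough <- i >= 3L && (p1v - p2v) < 0 && (pitch - p1v) >= 0
    roll_peak <- i >= 3L && (r1v - r2v) > 0 && (roll - r1v) <= 0
    facc_peak <- i >= 3L && (f1v - f2v) > 0 && (facc - f1v) <= 0

    if (phase == "rest") {
      still <- (na_ < params$a_rest) && (nw_ < params$w_rest)
      if (still) off <- update_rest_offsets(off, k$a_g, k$w_g, k$euler, TRUE)
      cnt_a <- if (!still) cnt_a + 1L else 0L
      if (cnt_a >= params$n_r) {
        phases[[length(phases) + 1L]] <- list(phase = "rest",
                                              t_start = phase_start,
                                              t_end = tt[i])
        phase <- "unrest"; phase_start <- tt[i]
        cnt_a <- 0L
        z_active <- TRUE
        off <- update_rest_offsets(off, k$a_g, k$w_g, k$euler, FALSE)
        last_roll_max_t <- NA_real_; last_facc_max_t <- NA_real_
      }
    } else { # unrest
      still <- (na_ < params$a_rest) && (nw_ < params$w_rest)
      cnt_a <- if (still) cnt_a + 1L else 0L
      if (cnt_a >= params$n_r) {
        if (in_motion) close_motion(tt[i], "truncated", truncated = TRUE)
        phases[[length(phases) + 1L]] <- list(phase = "unrest",
                                              t_start = phase_start,
                                              t_end = tt[i])
        phase <- "rest"; phase_start <- tt[i]
        cnt_a <- 0L
        z_active <- FALSE
        rest_since_end <- TRUE
      } else if (in_motion) {
        # strap-down velocity (trapezoid) inside the motion phase
        v <- v + 0.5 * (prev_adg + k$a_dg) * dt
        vmax_x <- max(vmax_x, abs(v[1L])); vmax_y <- max(vmax_y, abs(v[2L]))
        if (tt[i] > t0 + params$t_mot) {
          d1 <- max_jerk_prev > 0 && jerk > params$alpha * max_jerk_prev
          d2 <- abs(v[1L]) < params$beta * vmax_x &&
            abs(v[2L]) < params$beta * vmax_y
          if (d1 && d2) {
            close_motion(tt[i], "jerk_velocity")
          } else if (pitch_trough && abs(r1v) < phi_r &&
                     abs(p1v) < kappa * pitch_max) {
            close_motion(tt[i - 1L], "pitch_min")
          }
        }
        if (in_motion) {
          max_jerk_prev <- max(max_jerk_prev, jerk)
          pitch_max <- max(pitch_max, pitch)
        }
      } else if (z_active) {
        started <- FALSE
        if (pitch_peak && p1v > phi_p) {
          t0 <- tt[i - 1L]; i0 <- i - 1L; start_rule <- "pitch_max"
          pitch_max <- p1v
          started <- TRUE
        } else {
          if (roll_peak) last_roll_max_t <- tt[i - 1L]
          if (facc_peak && f1v > params$a_s) last_facc_max_t <- tt[i - 1L]
          if (!is.na(last_roll_max_t) && !is.na(last_facc_max_t) &&
              abs(last_roll_max_t - last_facc_max_t) <= params$delta) {
            t0 <- max(last_roll_max_t, last_facc_max_t)
            i0 <- i - 1L; start_rule <- "roll_acc_corr"
            pitch_max <- pitch
            started <- TRUE
          }
        }
        if (started) {
          in_motion <- TRUE
          max_jerk_prev <- jerk
          v <- c(0, 0, 0); vmax_x <- 0; vmax_y <- 0
          last_roll_max_t <- NA_real_; last_facc_max_t <- NA_real_
        }
      } else if (z_reactivation && !rest_since_end &&
                 tt[i] > motion_end_t + params$t_x) {
        if (params$f_on_angles) {
          f_ok <- abs(pitch) < p1 && abs(roll) < p1
        } else {
          f_ok <- i >= 2L && abs(pitch - p1v) / dt < p1 &&
            abs(roll - r1v) / dt < p1
        }
        cnt_f <- if (f_ok) cnt_f + 1L else 0L
        g_ok <- length(raw_buf) >= params$n_r && stats::var(raw_buf) < params$p2
        cnt_g <- if (g_ok) cnt_g + 1L else 0L
        h_ok <- pitch_peak && p1v > phi_thres
        rule <- if (h_ok) "H"
        else if (cnt_f >= params$n_r) "F"
        else if (cnt_g >= params$n_r) "G"
        else NA_character_
        if (!is.na(rule)) {
          z_active <- TRUE
          cnt_f <- 0L; cnt_g <- 0L
          zreact[[length(zreact) + 1L]] <- list(t = tt[i], rule = rule)
        }
      }
    }

    tr[i, ] <- c(if (phase == "rest") 1 else 2, as.numeric(in_motion),
                 as.numeric(z_active), pitch, roll, yaw, k$a_dg, jerk,
                 v[1L], v[2L], na_, nw_, facc, raw_norm)
    prev_adg <- k$a_dg
  }

  if (in_motion) close_motion(tt[n], "truncated", truncated = TRUE)
  phases[[length(phases) + 1L]] <- list(phase = phase, t_start = phase_start,
                                        t_end = tt[n])

  phases_df <- do.call(rbind, lapply(phases, as.data.frame))
  motion_df <- if (length(motion)) do.call(rbind, lapply(motion, as.data.frame))
  else data.frame(t_start = numeric(0), t_end = numeric(0),
                  start_rule = character(0), end_rule = character(0),
                  truncated = logical(0))
  z_df <- if (length(zreact)) do.call(rbind, lapply(zreact, as.data.frame))
  else data.frame(t = numeric(0), rule = character(0))

  res <- list(phases = phases_df, motion = motion_df, z_reactivations = z_df,
              fs = series$fs, foot = series$foot,
              subject_id = series$subject_id, params = params)
  if (keep_trace) res$trace <- cbind(data.frame(t = tt), as.data.frame(tr))
  structure(res, class = "phase_sequence")
}

#' @export
print.phase_sequence <- function(x, ...) {
  cat(sprintf(
    "Phase sequence: %d rest/unrest intervals, %d motion phases, %d Z reactivations\n",
    nrow(x$phases), nrow(x$motion), nrow(x$z_reactivations)))
  invisible(x)
}
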