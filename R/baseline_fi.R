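# Spectral freezing-index baseline: ratio of freeze-band (3-8 Hz) to
# locomotor-band power of an acceleration channel over a trailing
# window.

.band_power <- function(pxx, freqs, lo, hi) {
  sum(pxx[freqs >= lo & freqs < hi])
}

#' Freezing index over trailing windows
#'
#' For each trailing window the signal is linearly detrended, tapered
#' with a Hann window, and its periodogram power summed over the freeze
#' band `[3, 8)` Hz and the locomotor band `[locomotor_lo, 3)` Hz; the
#' freezing index is their ratio. The locomotor band's lower edge
#' defaults to 0.5 Hz to exclude the DC/trend bin (set
#' `locomotor_lo = 0` for the literal 0-3 Hz band). Windows are causal
#' and advance by `step` samples.
#'
#' @param x numeric signal (one channel).
#' @param fs sampling rate, Hz.
#' @param window_s window length, s; `window_s * fs >= 16` samples.
#' @param step window advance in samples (default 1).
#' @param locomotor_lo lower edge of the locomotor band, Hz.
#' @return data.frame with `t_end` (window end time, s, first sample at
#'   time 0) and `fi` (`Inf` when the locomotor power vanishes).
#' @export
freezing_index <- function(x, fs, window_s = 6, step = 1L,
                           locomotor_lo = 0.5) {
  nw <- round(window_s * fs)
  if (nw < 16L) stop("window too short: need window_s * fs >= 16", call. = FALSE)
  n <- length(x)
  if (n < nw) stop("signal shorter than one window", call. = FALSE)
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))
  freqs <- (seq_len(nw) - 1) / nw * fs
  idx_t <- seq_len(nw) - mean(seq_len(nw))
  ends <- seq(nw, n, by = step)
  fi <- numeric(length(ends))
  for (k in seq_along(ends)) {
    seg <- x[(ends[k] - nw + 1L):ends[k]]
    # linear detrend
    beta <- sum(idx_t * seg) / sum(idx_t^2)
    seg <- seg - mean(seg) - beta * idx_t
    pxx <- Mod(stats::fft(seg * hann))^2
    pf <- .band_power(pxx, freqs, 3, 8)
    pl <- .band_power(pxx, freqs, locomotor_lo, 3)
    # vanishing locomotor power: 0 for a silent window (no freeze either),
    # +Inf sentinel when freeze-band power is present
    fi[k] <- if (pl < .Machine$double.eps) {
      if (pf < .Machine$double.eps) 0 else Inf
    } else pf / pl
  }
  data.frame(t_end = (ends - 1) / fs, fi = fi)
}

#' Threshold detection on a freezing-index series
#'
#' @param fi_series data.frame from [freezing_index()].
#' @param threshold positive FI threshold.
#' @return integer labels per window (1 = FoG, i.e. FI above threshold).
#' @export
fi_detect <- function(fi_series, threshold) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  as.integer(fi_series$fi > threshold)
}

#' Majority vote of per-axis freezing indices over all six channels
#'
#' Computes the freezing index separately for each of the six IMU
#' channels and flags a window as FoG when at least `min_votes` of the
#' six per-axis indices exceed the common threshold (strict majority of
#' six, i.e. >= 4, by default).
#'
#' @param series an [imu_series()].
#' @param window_s,step,locomotor_lo see [freezing_index()].
#' @param threshold common FI threshold.
#' @param min_votes votes required for a FoG call.
#' @return data.frame with `t_end`, per-axis vote count `votes`, and
#'   `label`.
#' @export
fi_multiaxis_vote <- function(series, window_s = 6, threshold = 1,
                              step = 1L, locomotor_lo = 0.5, min_votes = 4L) {
  stopifnot(inherits(series, "imu_series"))
  chans <- cbind(series$acc, series$gyro)
  labs <- lapply(seq_len(6L), function(j) {
    fi <- freezing_index(chans[, j], series$fs, window_s, step, locomotor_lo)
    list(t_end = fi$t_end, lab = fi_detect(fi, threshold))
  })
  votes <- Reduce(`+`, lapply(labs, `[[`, "lab"))
  data.frame(t_end = labs[[1L]]$t_end + series$t[1L], votes = votes,
             label = as.integer(votes >= min_votes))
}
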