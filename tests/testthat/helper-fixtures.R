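# Shared fixtures and independent oracles.

# Write a 7-column IMU CSV; gyro_unit "rad/s" or "deg/s".
write_imu_fixture <- function(path, t, acc, gyro, gyro_unit = "rad/s") {
  hdr <- sprintf(
    "t[s],ax[m/s^2],ay[m/s^2],az[m/s^2],gx[%s],gy[%s],gz[%s]",
    gyro_unit, gyro_unit, gyro_unit)
  m <- cbind(t, acc, gyro)
  lines <- apply(m, 1L, function(r) paste(format(r, digits = 17), collapse = ","))
  writeLines(c(hdr, lines), path)
  path
}

# Brute-force AUC by exhaustive pair counting (ties count one half).
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Quiet rest series of given duration (exact gravity, no noise).
rest_series <- function(duration = 5, fs = 200) {
  n <- round(duration * fs)
  imu_series(t = (seq_len(n) - 1) / fs,
             acc = matrix(rep(c(0, 0, 9.81), each = n), n, 3L),
             gyro = matrix(0, n, 3L), fs = fs)
}

# Total rest duration of a phase sequence.
rest_duration <- function(ps) {
  with(ps$phases, sum((t_end - t_start)[phase == "rest"]))
}
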