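#' Construct an IMU time series
#'
#' Container for one foot's six-channel inertial recording on a uniform
#' time grid: specific force (gravity-bearing linear acceleration) and
#' angular rate in the sensor frame.
#'
#' @param t sample times in seconds, strictly increasing with constant
#'   step `1/fs` (tolerance 1e-6 s).
#' @param acc n x 3 matrix, m/s^2, sensor frame, gravity included.
#' @param gyro n x 3 matrix, rad/s, sensor frame.
#' @param fs sampling rate in Hz.
#' @param foot `"left"` or `"right"`.
#' @param subject_id subject identifier string.
#' @return object of class `imu_series`.
#' @export
imu_series <- function(t, acc, gyro, fs, foot = "left", subject_id = "S0") {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  t <- as.numeric(t)
  if (ncol(acc) != 3L || ncol(gyro) != 3L)
    stop("acc and gyro must have 3 columns", call. = FALSE)
  if (nrow(acc) != length(t) || nrow(gyro) != length(t))
    stop("acc and gyro must have one row per time stamp", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  foot <- match.arg(foot, c("left", "right"))
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0) || any(abs(dt - 1 / fs) > 1e-6))
      stop("sampling error: time stamps must increase with constant step 1/fs",
           call. = FALSE)
  }
  structure(list(t = t, acc = unname(acc), gyro = unname(gyro), fs = fs,
                 foot = foot, subject_id = as.character(subject_id)),
            class = "imu_series")
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("IMU series: %d samples @ %g Hz (%.2f s), foot=%s, subject=%s\n",
              length(x$t), x$fs, if (length(x$t)) diff(range(x$t)) else 0,
              x$foot, x$subject_id))
  invisible(x)
}

.imu_header <- "t[s],ax[m/s^2],ay[m/s^2],az[m/s^2],gx[rad/s],gy[rad/s],gz[rad/s]"

#' Read an IMU recording from CSV
#'
#' Expects seven comma-separated columns `t, ax, ay, az, gx, gy, gz`
#' with a single header line carrying units in square brackets, e.g.
#' `t[s],ax[m/s^2],...,gx[rad/s]`. Gyroscope columns declared in
#' `deg/s` are converted to rad/s on read.
#'
#' @param path file path.
#' @param fs_expected expected sampling rate in Hz; the uniform grid is
#'   validated against it.
#' @param foot,subject_id metadata attached to the returned series.
#' @return an [imu_series()].
#' @export
read_imu_recording <- function(path, fs_expected, foot = "left",
                               subject_id = "S0") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  hdr <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(hdr) != 7L)
    stop("header must declare 7 columns (t, ax, ay, az, gx, gy, gz)",
         call. = FALSE)
  gyro_deg <- any(grepl("deg/s", hdr[5:7], fixed = TRUE))
  body <- lines[-1L][nzchar(lines[-1L])]
  n <- length(body)
  if (n == 0L)
    stop("no data rows in ", path, call. = FALSE)
  vals <- matrix(NA_real_, n, 7L)
  for (i in seq_len(n)) {
    fld <- strsplit(body[[i]], ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(fld))
    if (length(num) != 7L || anyNA(num))
      stop(sprintf("parse error at line %d of %s", i + 1L, path), call. = FALSE)
    vals[i, ] <- num
  }
  t <- vals[, 1L]
  if (n >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0) || any(abs(dt - 1 / fs_expected) > 1e-6))
      stop(sprintf("sampling error in %s: timestamps not a uniform %g Hz grid",
                   path, fs_expected), call. = FALSE)
  }
  gyro <- vals[, 5:7]
  if (gyro_deg) gyro <- gyro * pi / 180
  imu_series(t, vals[, 2:4], gyro, fs = fs_expected, foot = foot,
             subject_id = subject_id)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_recording()]; always writes rad/s.
#'
#' @param series an [imu_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu_recording <- function(series, path) {
  stopifnot(inherits(series, "imu_series"))
  m <- cbind(series$t, series$acc, series$gyro)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.imu_header, con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.fog_subtypes <- c("festination", "shuffling", "trembling", "akinesia")

#' Read expert FoG annotations
#'
#' CSV with columns `start,end,subtype,rater`; times in seconds on the
#' recording clock. Episodes are returned sorted by start time.
#' Overlapping episodes from the same rater are allowed.
#'
#' @param path file path.
#' @return data.frame with columns `start`, `end`, `subtype`, `rater`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "subtype", "rater")
  if (!all(need %in% names(df)))
    stop("annotation file must have columns start,end,subtype,rater",
         call. = FALSE)
  df <- df[, need, drop = FALSE]
  validate_annotations(df)
}

validate_annotations <- function(df) {
  if (nrow(df) == 0L) return(df)
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("non-numeric episode bounds", call. = FALSE)
  if (any(df$end <= df$start))
    stop("validation error: episode end must exceed start", call. = FALSE)
  bad <- setdiff(unique(df$subtype), .fog_subtypes)
  if (length(bad))
    stop("validation error: unknown subtype(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df[order(df$start), , drop = FALSE]
}

#' Write FoG annotations
#' @param episodes data.frame as returned by [read_annotations()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(episodes, path) {
  utils::write.csv(episodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phase sequence to JSON
#'
#' Exports the rest/unrest partition with nested motion phases as a
#' list of `{"phase", "t_start", "t_end", "motion_phases": [...]}`.
#'
#' @param ps a `phase_sequence` from [segment_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phase_json <- function(ps, path) {
  stopifnot(inherits(ps, "phase_sequence"))
  out <- lapply(seq_len(nrow(ps$phases)), function(i) {
    row <- ps$phases[i, ]
    mp <- ps$motion[ps$motion$t_start >= row$t_start - 1e-12 &
                      ps$motion$t_end <= row$t_end + 1e-12, , drop = FALSE]
    list(phase = row$phase, t_start = row$t_start, t_end = row$t_end,
         motion_phases = lapply(seq_len(nrow(mp)), function(j)
           as.list(mp[j, c("t_start", "t_end", "start_rule", "end_rule",
                           "truncated")])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a motion-phase feature table
#'
#' One row per completed motion phase: metadata (`subject`, `foot`,
#' `t_end`) followed by the ten features in their canonical order.
#'
#' @param features data.frame from [extract_feature_table()].
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(format(features, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}
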