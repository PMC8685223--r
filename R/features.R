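# Spatio-temporal features of a completed motion phase.

# Unwrap a wrapped angle series (jumps > pi are 2*pi crossings).
.unwrap <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  d <- d - 2 * pi * round(d / (2 * pi))
  x[1L] + c(0, cumsum(d))
}

.feature_names <- c("max_acc_norm", "max_pitch", "min_pitch", "stride_length",
                    "max_velocity", "turning_angle", "turned_flag",
                    "max_turn_rate", "mean_turn_rate", "step_duration")

#' Canonical feature order
#'
#' The ten per-motion-phase features, in the fixed order used by all
#' feature tables and design matrices.
#' @return character vector of length 10.
#' @export
feature_names <- function() .feature_names

#' Strap-down velocity integration over one motion phase
#'
#' Cumulative trapezoidal integration of the detrended, gravity-free
#' global acceleration, starting from zero velocity at the motion-phase
#' start.
#'
#' @param a_dg n x 3 matrix (or n x k) of acceleration samples, m/s^2.
#' @param dt sampling interval, s.
#' @return matrix of the same shape: velocity, m/s.
#' @export
integrate_motion_velocity <- function(a_dg, dt) {
  a_dg <- as.matrix(a_dg)
  if (nrow(a_dg) == 0L) stop("empty motion segment", call. = FALSE)
  v <- apply(a_dg, 2L, function(a) {
    if (length(a) == 1L) return(0)
    c(0, cumsum(0.5 * (a[-length(a)] + a[-1L]) * dt))
  })
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  v
}

#' Zero-end-velocity drift correction
#'
#' Enforces the biomechanical constraint that the foot is at rest at the
#' end of a motion phase: a linear-in-time offset ramp is subtracted per
#' axis so the final velocity is exactly zero (equivalent to removing a
#' constant accelerometer bias over the phase). The integrated part of
#' the ramp is likewise removed from the displacement, so the stride
#' vector is the integral of the corrected horizontal velocity.
#'
#' @param v n x 3 velocity matrix from [integrate_motion_velocity()].
#' @param dt sampling interval, s.
#' @return list with `v` (corrected velocity), `stride_vec`
#'   (displacement 3-vector from the corrected velocity) and
#'   `stride_length` (Euclidean norm of its x-y part), m.
#' @export
correct_velocity_drift <- function(v, dt) {
  v <- as.matrix(v)
  n <- nrow(v)
  if (n == 0L) stop("empty velocity series", call. = FALSE)
  ramp <- if (n > 1L) (seq_len(n) - 1) / (n - 1) else 0
  vc <- v - outer(ramp, v[n, ])
  disp <- apply(vc, 2L, function(x)
    if (n > 1L) sum(0.5 * (x[-n] + x[-1L]) * dt) else 0)
  list(v = vc, stride_vec = disp,
       stride_length = sqrt(sum(disp[1:2]^2)))
}

#' Turning detection from the yaw angle of one motion phase
#'
#' A motion phase counts as a turn when the yaw angle, referenced to the
#' phase start, changes monotonically (within a tolerance) without
#' re-crossing zero after leaving it, and ends beyond the tolerance.
#' The turning angle (final yaw minus initial yaw) is always reported.
#'
#' @param yaw yaw-angle series of the phase, radians.
#' @param eps_yaw monotonicity/zero-band tolerance, radians
#'   (default 1 degree).
#' @return list with `turned_flag` (0/1) and `turning_angle` (rad).
#' @export
detect_turning <- function(yaw, eps_yaw = pi / 180) {
  y <- yaw - yaw[1L]
  ang <- y[length(y)]
  if (length(y) < 2L) return(list(turned_flag = 0L, turning_angle = ang))
  d <- diff(y)
  mono_up <- all(d >= -eps_yaw)
  mono_dn <- all(d <= eps_yaw)
  left <- which(abs(y) > eps_yaw)[1L]
  recross <- FALSE
  if (!is.na(left) && left < length(y)) {
    s0 <- sign(y[left])
    recross <- any(sign(y[(left + 1L):length(y)]) == -s0 &
                     abs(y[(left + 1L):length(y)]) > .Machine$double.eps)
  }
  flag <- as.integer((mono_up || mono_dn) && !is.na(left) && !recross &&
                       abs(ang) > eps_yaw)
  list(turned_flag = flag, turning_angle = ang)
}

#' Extract the ten features of one motion phase
#'
#' Computes, from the kinematic trace restricted to one motion phase:
#' the maximum detrended acceleration norm; maximum and minimum pitch;
#' stride length and maximum horizontal gait speed after strap-down
#' integration with zero-end-velocity drift correction; turning angle
#' and turned flag from the yaw angle; maximum and mean absolute yaw
#' rate; and the step (motion-phase) duration.
#'
#' @param segment data.frame slice of a `phase_sequence` trace covering
#'   exactly `[t_start, t_end]` of the phase (columns `t`, `adgx..adgz`,
#'   `pitch_d`, `roll_d`, `yaw_d`).
#' @param t_start,t_end phase boundaries, s.
#' @param fs sampling rate, Hz.
#' @return named numeric vector of the 10 features (angles in radians).
#' @export
extract_features <- function(segment, t_start, t_end, fs) {
  if (nrow(segment) == 0L)
    stop("segment/phase mismatch: empty segment", call. = FALSE)
  if (segment$t[1L] < t_start - 1e-9 ||
      segment$t[nrow(segment)] > t_end + 1e-9)
    stop("segment/phase mismatch: segment exceeds phase bounds", call. = FALSE)
  dt <- 1 / fs
  a <- as.matrix(segment[, c("adgx", "adgy", "adgz")])
  acc_norm <- sqrt(rowSums(a^2))
  v <- integrate_motion_velocity(a, dt)
  cv <- correct_velocity_drift(v, dt)
  speed_xy <- sqrt(cv$v[, 1L]^2 + cv$v[, 2L]^2)
  yaw <- .unwrap(segment$yaw_d) # heading may cross +-180 deg mid-phase
  turn <- detect_turning(yaw)
  yaw_rate <- if (nrow(segment) > 1L) abs(diff(yaw)) / dt else 0
  c(max_acc_norm = max(acc_norm),
    max_pitch = max(segment$pitch_d),
    min_pitch = min(segment$pitch_d),
    stride_length = cv$stride_length,
    max_velocity = max(speed_xy),
    turning_angle = turn$turning_angle,
    turned_flag = as.numeric(turn$turned_flag),
    max_turn_rate = max(yaw_rate),
    mean_turn_rate = mean(yaw_rate),
    step_duration = t_end - t_start)
}

#' Feature table for all motion phases of a recording
#'
#' @param ps a `phase_sequence` from [segment_recording()] with its
#'   trace kept.
#' @return data.frame with metadata columns `subject`, `foot`, `t_end`
#'   followed by the 10 features.
#' @export
extract_feature_table <- function(ps) {
  stopifnot(inherits(ps, "phase_sequence"))
  if (is.null(ps$trace))
    stop("phase_sequence has no trace; rerun segment_recording(keep_trace=TRUE)",
         call. = FALSE)
  mp <- ps$motion
  rows <- lapply(seq_len(nrow(mp)), function(j) {
    seg <- ps$trace[ps$trace$t >= mp$t_start[j] - 1e-9 &
                      ps$trace$t <= mp$t_end[j] + 1e-9, , drop = FALSE]
    extract_features(seg, mp$t_start[j], mp$t_end[j], ps$fs)
  })
  feat <- if (length(rows)) as.data.frame(do.call(rbind, rows))
  else as.data.frame(matrix(numeric(0), 0L, 10L,
                            dimnames = list(NULL, .feature_names)))
  cbind(data.frame(subject = rep(ps$subject_id, nrow(feat)),
                   foot = rep(ps$foot, nrow(feat)),
                   t_end = mp$t_end[seq_len(nrow(feat))]),
        feat)
}

#' Univariate chi-square feature ranking
#'
#' Each continuous feature is discretised into `n_bins` quantile bins
#' and tested for independence against the binary label with a Pearson
#' chi-square test (no continuity correction). The importance is
#' `-log10(p)`; importances above `-log10(0.05) ~ 1.3` mark a feature as
#' relevant at the 5% level.
#'
#' @param X data.frame or matrix of features (columns ranked
#'   individually).
#' @param y binary labels (two classes, any coding), at least two
#'   samples per class.
#' @param n_bins number of quantile bins for continuous features.
#' @return data.frame sorted by decreasing importance with columns
#'   `feature`, `chi_sq`, `df`, `p_value`, `importance`, `relevant`,
#'   `rank`.
#' @export
rank_features <- function(X, y, n_bins = 10L) {
  X <- as.data.frame(X)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (min(table(y)) < 2L) stop("need at least 2 samples per class", call. = FALSE)
  res <- lapply(names(X), function(nm) {
    x <- X[[nm]]
    ux <- unique(x)
    if (length(ux) < 2L) {
      warning("constant feature '", nm, "': importance set to 0")
      return(data.frame(feature = nm, chi_sq = 0, df = 0, p_value = 1,
                        importance = 0))
    }
    bins <- if (length(ux) <= n_bins) {
      factor(x)
    } else {
      br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE, type = 7))
      cut(x, breaks = br, include.lowest = TRUE)
    }
    tab <- table(bins, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi <- sum((tab - exp_)^2 / exp_)
    df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    p <- stats::pchisq(chi, df, lower.tail = FALSE)
    data.frame(feature = nm, chi_sq = chi, df = df, p_value = p,
               importance = -log10(max(p, .Machine$double.xmin)))
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$importance), , drop = FALSE]
  out$relevant <- out$importance > -log10(0.05)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Build a (possibly lagged) design matrix from motion-phase features
#'
#' Stacks per-phase feature rows into classifier inputs. Variant `C0`
#' uses the current phase only (10 columns); `C210` appends the two
#' preceding phases (30 columns); `C21` uses only the two preceding
#' phases (20 columns) with the label taken from the current phase, i.e.
#' a one-phase-ahead prediction target. Lag stacking never crosses a
#' subject or foot boundary; rows lacking the required predecessors are
#' dropped.
#'
#' @param rows data.frame with columns `subject`, `foot`, `t_end`, the
#'   10 features, and optionally `label`.
#' @param variant `"C0"`, `"C210"`, or `"C21"`.
#' @param features feature columns to use (default all ten).
#' @return list with matrix `X` (lag-suffixed column names), vector `y`
#'   (`NULL` when `rows` has no `label`), and data.frame `meta`
#'   (subject, foot, t_end of the target phase).
#' @export
build_design_matrix <- function(rows, variant = c("C0", "C210", "C21"),
                                features = feature_names()) {
  variant <- match.arg(variant)
  lags <- switch(variant, C0 = 0L, C210 = c(0L, 1L, 2L), C21 = c(1L, 2L))
  maxlag <- max(lags)
  has_label <- "label" %in% names(rows)
  grp <- interaction(rows$subject, rows$foot, drop = TRUE)
  Xs <- list(); ys <- list(); metas <- list()
  for (g in levels(grp)) {
    sub <- rows[grp == g, , drop = FALSE]
    sub <- sub[order(sub$t_end), , drop = FALSE]
    n <- nrow(sub)
    if (n <= maxlag) next
    idx <- (maxlag + 1L):n
    blocks <- lapply(lags, function(l) {
      b <- as.matrix(sub[idx - l, features, drop = FALSE])
      colnames(b) <- paste0(features, "_lag", l)
      b
    })
    Xs[[g]] <- do.call(cbind, blocks)
    if (has_label) ys[[g]] <- sub$label[idx]
    metas[[g]] <- sub[idx, c("subject", "foot", "t_end"), drop = FALSE]
  }
  if (!length(Xs)) {
    warning("not enough phases for variant ", variant, ": empty design matrix")
    empty_cols <- unlist(lapply(lags, function(l) paste0(features, "_lag", l)))
    return(list(X = matrix(numeric(0), 0L, length(empty_cols),
                           dimnames = list(NULL, empty_cols)),
                y = if (has_label) numeric(0) else NULL,
                meta = rows[0L, c("subject", "foot", "t_end")]))
  }
  list(X = do.call(rbind, Xs),
       y = if (has_label) unlist(ys, use.names = FALSE) else NULL,
       meta = do.call(rbind, metas))
}
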