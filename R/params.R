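#' Gait-phase-detection parameters
#'
#' Constructs the parameter set of the rest/unrest/motion state machine.
#' Defaults are the published operating point used for all patients;
#' angles are given in degrees and converted internally.
#'
#' @param a_rest rest bound on the detrended global acceleration norm
#'   (m/s^2).
#' @param w_rest rest bound on the detrended global angular-rate norm
#'   (rad/s).
#' @param delta maximum time displacement between the roll-angle maximum
#'   and the filtered-acceleration-norm maximum in the alternative
#'   motion-start condition (s).
#' @param n_r debounce length: consecutive samples required for
#'   rest/unrest transitions and for the Z-reactivation conditions F/G.
#' @param phi_p lower bound on a pitch-angle local maximum that starts a
#'   motion phase (deg).
#' @param phi_r roll-angle bound in the pitch-minimum motion-end
#'   condition E (deg).
#' @param a_s minimum height of the filtered acceleration-norm peak in
#'   the alternative motion-start condition (m/s^2).
#' @param t_x interval after a motion-phase end with no rest phase after
#'   which Z reactivation is considered (s).
#' @param n_a moving-average window (samples) applied to the
#'   acceleration norm before peak detection.
#' @param alpha jerk factor of motion-end condition D1: the current jerk
#'   norm must exceed `alpha` times the running maximum.
#' @param beta velocity factor of motion-end condition D2: both
#'   horizontal velocity components must fall below `beta` times their
#'   running maxima.
#' @param kappa pitch factor of motion-end condition E: the local pitch
#'   minimum must be smaller in magnitude than `kappa` times the maximum
#'   pitch of the phase.
#' @param p1 stillness bound of Z-reactivation condition F on the pitch
#'   and roll angular rates (deg/s). Set `f_on_angles = TRUE` to compare
#'   the angles themselves (deg) instead, the literal printed form.
#' @param p2 bound of Z-reactivation condition G on the sliding variance
#'   of the raw acceleration norm (m^2/s^4).
#' @param phi_thres pitch local-maximum threshold of Z-reactivation
#'   condition H (deg).
#' @param t_mot minimum elapsed motion-phase duration before the end
#'   conditions are evaluated (s).
#' @param n_d moving-average window (samples) for rest-phase offset
#'   estimation.
#' @param f_on_angles logical; compare condition F against angles rather
#'   than angular rates (default `FALSE`, the rate reading).
#' @return object of class `gpd_params`.
#' @export
gpd_params <- function(a_rest = 0.5, w_rest = 0.11, delta = 0.25, n_r = 10,
                       phi_p = 1, phi_r = 5, a_s = 2, t_x = 0.1, n_a = 7,
                       alpha = 1.2, beta = 0.6, kappa = 0.8, p1 = 0.75,
                       p2 = 1.5, phi_thres = 15, t_mot = 0.075, n_d = 10,
                       f_on_angles = FALSE) {
  p <- list(a_rest = a_rest, w_rest = w_rest, delta = delta, n_r = n_r,
            phi_p = phi_p, phi_r = phi_r, a_s = a_s, t_x = t_x, n_a = n_a,
            alpha = alpha, beta = beta, kappa = kappa, p1 = p1, p2 = p2,
            phi_thres = phi_thres, t_mot = t_mot, n_d = n_d,
            f_on_angles = isTRUE(f_on_angles))
  validate_gpd_params(p)
  structure(p, class = "gpd_params")
}

validate_gpd_params <- function(p) {
  num <- setdiff(names(p), "f_on_angles")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  for (nm in c("n_r", "n_a", "n_d")) {
    if (p[[nm]] != round(p[[nm]]) || p[[nm]] < 1)
      stop(sprintf("parameter '%s' must be a positive integer", nm), call. = FALSE)
  }
  if (p$alpha <= 1) stop("alpha must be > 1", call. = FALSE)
  if (p$beta >= 1) stop("beta must be in (0, 1)", call. = FALSE)
  if (p$kappa > 1) stop("kappa must be in (0, 1]", call. = FALSE)
  invisible(p)
}

#' Load gait-phase-detection parameters from file
#'
#' Reads an optional YAML or JSON override file; any subset of the
#' parameters of [gpd_params()] may be given, the remainder keep their
#' defaults. The merged set is re-validated.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   defaults.
#' @return object of class `gpd_params`.
#' @export
load_gpd_params <- function(path = NULL) {
  if (is.null(path)) return(gpd_params())
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ov <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(ov)) {
    bad <- setdiff(names(ov), names(formals(gpd_params)))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(gpd_params, as.list(ov))
}

#' @export
print.gpd_params <- function(x, ...) {
  cat("Gait-phase-detection parameters:\n")
  for (nm in setdiff(names(x), "f_on_angles"))
    cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  cat(sprintf("  condition F compares %s\n",
              if (x$f_on_angles) "angles (deg)" else "angular rates (deg/s)"))
  invisible(x)
}
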