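#' Calibrate the amyloid-load transfer function
#'
#' Builds the sigmoid transfer that maps amyloid-beta load (a PET SUVR
#' scalar, `beta_a`) onto the inhibitory synaptic rate. The slope and
#' midpoint are derived from clinical anchor points:
#' `r_beta = 2*log(s_max) / (beta_off - beta_max)` (positive, since
#' `s_max < 1` and `beta_off < beta_max`) and
#' `beta0 = (beta_off + beta_max) / 2`.
#'
#' @param beta_off Clinical SUVR cutoff separating normal from pathological
#'   load (default 1.4).
#' @param beta_max Maximum population SUVR (default 2.65).
#' @param s_max Maximum of the transfer function; its reciprocal is the
#'   amyloid-free inhibitory time constant in ms (default 0.07, i.e.
#'   14.29 ms).
#' @param s_min Minimum of the transfer function; its reciprocal is the
#'   fully saturated inhibitory time constant in ms (default 0.02, i.e.
#'   50 ms).
#' @return An object of class `"abeta_calibration"` with fields `beta_off`,
#'   `beta_max`, `s_max`, `s_min` and the derived `r_beta`, `beta0`.
#' @seealso [abeta_transfer()], [tau_inhibitory()]
#' @examples
#' cal <- abeta_calibration()
#' cal$beta0    # 2.025
#' cal$r_beta   # 2*log(0.07)/(1.4 - 2.65)
#' @export
abeta_calibration <- function(beta_off = 1.4, beta_max = 2.65,
                              s_max = 0.07, s_min = 0.02) {
  for (nm in c("beta_off", "beta_max", "s_max", "s_min")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop(sprintf("`%s` must be a finite scalar", nm), call. = FALSE)
  }
  if (!(beta_off < beta_max))
    stop("`beta_off` must be smaller than `beta_max`", call. = FALSE)
  if (!(s_min > 0))
    stop("`s_min` must be positive", call. = FALSE)
  if (!(s_min < s_max))
    stop("`s_min` must be smaller than `s_max`", call. = FALSE)
  if (!(s_max < 1))
    stop("`s_max` must be below 1 (so the calibrated slope is positive)",
         call. = FALSE)
  cal <- list(beta_off = beta_off, beta_max = beta_max,
              s_max = s_max, s_min = s_min,
              r_beta = 2 * log(s_max) / (beta_off - beta_max),
              beta0 = (beta_off + beta_max) / 2)
  class(cal) <- "abeta_calibration"
  cal
}

#' @export
print.abeta_calibration <- function(x, ...) {
  cat("Amyloid-load transfer calibration\n")
  cat(sprintf("  anchors:  beta_off = %.4g, beta_max = %.4g (SUVR)\n",
              x$beta_off, x$beta_max))
  cat(sprintf("  range:    S in (%.4g, %.4g)  =>  tau_i in (%.4g, %.4g) ms\n",
              x$s_min, x$s_max, 1 / x$s_max, 1 / x$s_min))
  cat(sprintf("  derived:  slope r_beta = %.6g, midpoint beta0 = %.6g\n",
              x$r_beta, x$beta0))
  invisible(x)
}

#' Amyloid-load sigmoid transfer
#'
#' The continuously differentiable decreasing sigmoid
#' `S1(b) = s_min + (s_max - s_min) / (1 + exp(r_beta * (b - beta0)))`.
#' Strictly decreasing in the load, bounded in `(s_min, s_max)`, with
#' `S1(beta0) = (s_max + s_min)/2`.
#'
#' @param beta_a Amyloid load(s), SUVR.
#' @param cal An [abeta_calibration()] object.
#' @return Transfer value(s), strictly inside `(s_min, s_max)`.
#' @examples
#' abeta_transfer(2.025)   # midpoint: 0.045
#' @export
abeta_transfer <- function(beta_a, cal = abeta_calibration()) {
  stopifnot(inherits(cal, "abeta_calibration"))
  cal$s_min + (cal$s_max - cal$s_min) /
    (1 + exp(cal$r_beta * (beta_a - cal$beta0)))
}

#' Inhibitory time constant as a function of amyloid load
#'
#' Maps the amyloid load onto the TRN inhibitory synaptic time constant, in
#' ms. Below the clinical cutoff `beta_off` the time constant is clamped at
#' its amyloid-free value `1/s_max` (14.29 ms with the default calibration);
#' at and above the cutoff it is the reciprocal of the sigmoid transfer,
#' `1/S1(beta_a)`, rising towards `1/s_min` (50 ms) as load saturates. The
#' mapping is non-decreasing and stays inside `[1/s_max, 1/s_min]`.
#'
#' @param beta_a Amyloid load(s), SUVR; vectorized.
#' @param cal An [abeta_calibration()] object.
#' @return Inhibitory time constant(s), ms.
#' @examples
#' tau_inhibitory(c(0.001, 1.92, 2.10, 3.00))
#' @export
tau_inhibitory <- function(beta_a, cal = abeta_calibration()) {
  stopifnot(inherits(cal, "abeta_calibration"))
  if (!all(is.finite(beta_a)))
    stop("`beta_a` must be finite", call. = FALSE)
  ifelse(beta_a < cal$beta_off, 1 / cal$s_max,
         1 / abeta_transfer(beta_a, cal))
}

#' Clinical severity band of an amyloid load
#'
#' Bins a SUVR load into the clinical bands used to interpret the mapping:
#' below 1.4 `normal` (no pathology; time constant unaffected), 1.4-1.95
#' `moderate`, above 1.95 up to 2.15 `moderate_severe`, above 2.15 `severe`.
#'
#' @param beta_a Amyloid load(s), SUVR; vectorized.
#' @return A factor with levels `normal`, `moderate`, `moderate_severe`,
#'   `severe`.
#' @examples
#' severity_band(c(1.0, 1.5, 2.10, 3.0))
#' @export
severity_band <- function(beta_a) {
  if (!all(is.finite(beta_a)))
    stop("`beta_a` must be finite", call. = FALSE)
  lv <- c("normal", "moderate", "moderate_severe", "severe")
  out <- ifelse(beta_a < 1.4, "normal",
         ifelse(beta_a <= 1.95, "moderate",
         ifelse(beta_a <= 2.15, "moderate_severe", "severe")))
  factor(out, levels = lv)
}
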