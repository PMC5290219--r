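#' Preprocessing configuration
#'
#' Defaults follow the standard NIRS chain for slow hemodynamics: a 5th-order
#' Butterworth bandpass between 0.01 and 0.6 Hz (passing task-related
#' hemodynamics and Mayer/respiratory oscillations, rejecting cardiac
#' pulsation and DC), applied zero-phase, preceded by rest-baseline
#' subtraction and followed by linear then quadratic detrending.
#'
#' @param filter_order Butterworth order (per direction when zero-phase).
#' @param low_cut,high_cut band edges in Hz.
#' @param linear_detrend apply linear detrending after the filter.
#' @param poly_detrend_degree degree of the final polynomial detrend.
#' @param zero_phase apply the filter forward-backward (no group delay; the
#'   effective attenuation order doubles).
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(filter_order = 5L, low_cut = 0.01, high_cut = 0.6,
                              linear_detrend = TRUE, poly_detrend_degree = 2L,
                              zero_phase = TRUE) {
  if (filter_order < 1L) stop("filter_order must be >= 1", call. = FALSE)
  if (!(low_cut > 0 && low_cut < high_cut)) {
    stop("need 0 < low_cut < high_cut", call. = FALSE)
  }
  if (poly_detrend_degree < 0L) stop("poly_detrend_degree must be >= 0", call. = FALSE)
  structure(list(filter_order = as.integer(filter_order), low_cut = low_cut,
                 high_cut = high_cut, linear_detrend = isTRUE(linear_detrend),
                 poly_detrend_degree = as.integer(poly_detrend_degree),
                 zero_phase = isTRUE(zero_phase)),
            class = "preprocess_config")
}

#' Baseline normalization against the rest period
#'
#' Subtracts the mean of the rest interval from the whole series, so the
#' series is expressed as deviation from the participant's resting level.
#'
#' @param series numeric vector.
#' @param rest_interval 0-based half-open `[start, end)` sample interval.
#' @return The normalized series.
#' @export
baseline_normalize <- function(series, rest_interval) {
  check_interval(rest_interval, length(series), "rest interval")
  series - mean(slice_interval(series, rest_interval))
}

#' Butterworth bandpass filter
#'
#' @param series numeric vector.
#' @param sampling_rate Hz.
#' @param config a [preprocess_config()].
#' @return Filtered series, same length.
#' @export
bandpass <- function(series, sampling_rate, config = preprocess_config()) {
  nyq <- sampling_rate / 2
  if (config$high_cut >= nyq) {
    stop(sprintf("high_cut %g Hz must be below the Nyquist frequency %g Hz",
                 config$high_cut, nyq), call. = FALSE)
  }
  # filtfilt's edge padding needs a margin beyond the filter order.
  min_len <- 6L * (config$filter_order + 1L)
  if (length(series) <= min_len) {
    stop(sprintf("series too short for order-%d bandpass (need > %d samples)",
                 config$filter_order, min_len), call. = FALSE)
  }
  # Realized as a cascade of high-pass and low-pass Butterworth sections of
  # the configured order: a direct-form band-pass of this order with a
  # 0.01 Hz edge at fs = 10 Hz has poles so close to the unit circle that
  # double-precision filtering loses several digits; the cascade has the
  # same band edges and is numerically well conditioned.
  hp <- signal::butter(config$filter_order, config$low_cut / nyq, type = "high")
  lp <- signal::butter(config$filter_order, config$high_cut / nyq, type = "low")
  if (config$zero_phase) {
    signal::filtfilt(lp, signal::filtfilt(hp, series))
  } else {
    as.numeric(signal::filter(lp, signal::filter(hp, series)))
  }
}

#' Linear detrending
#'
#' Subtracts the least-squares straight line; the residual is orthogonal to
#' the constant and linear basis.
#'
#' @param series numeric vector of length >= 2.
#' @return Detrended series.
#' @export
detrend_linear <- function(series) {
  if (length(series) < 2L) {
    stop("linear detrend is underdetermined for length < 2", call. = FALSE)
  }
  t <- seq_along(series)
  stats::lm.fit(cbind(1, t), series)$residuals
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial of the given degree; degree 0 is
#' mean removal.
#'
#' @param series numeric vector.
#' @param degree polynomial degree (>= 0).
#' @return Detrended series.
#' @export
detrend_poly <- function(series, degree = 2L) {
  degree <- as.integer(degree)
  if (degree < 0L) stop("degree must be >= 0", call. = FALSE)
  if (length(series) <= degree) {
    stop(sprintf("degree-%d detrend is underdetermined for length %d",
                 degree, length(series)), call. = FALSE)
  }
  t <- seq_along(series) / length(series)  # scaled for conditioning
  basis <- outer(t, 0:degree, `^`)
  stats::lm.fit(basis, series)$residuals
}

#' Preprocess a recording
#'
#' Applies the full chain to every channel, in order: rest-baseline
#' normalization, Butterworth bandpass, linear detrend, polynomial detrend.
#' Block annotations are untouched.
#'
#' @param recording a `"nirs_recording"`.
#' @param config a [preprocess_config()].
#' @return The preprocessed recording.
#' @export
preprocess <- function(recording, config = preprocess_config()) {
  stopifnot(inherits(recording, "nirs_recording"))
  out <- recording
  for (j in seq_len(ncol(recording$channels))) {
    x <- recording$channels[, j]
    x <- baseline_normalize(x, recording$rest_interval)
    x <- bandpass(x, recording$sampling_rate, config)
    if (config$linear_detrend) x <- detrend_linear(x)
    x <- detrend_poly(x, config$poly_detrend_degree)
    out$channels[, j] <- x
  }
  out
}
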