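# Time-domain EMG feature bank: 19 features per muscle segment.
# Canonical order: LMAV, NSV, WL, WAMP, SSC, ZC, MOB, COM, SKW, AR1-AR4,
# m0, m2, m4, m6, AC1, AC2.

emg_feature_names <- function() {
  c("LMAV", "NSV", "WL", "WAMP", "SSC", "ZC", "MOB", "COM", "SKW",
    paste0("AR", 1:4), "m0", "m2", "m4", "m6", "AC1", "AC2")
}

#' Log of the mean absolute value
#'
#' `ln(mean(|x|))`. Raises an undefined-feature error on an all-zero segment.
#'
#' @param x Numeric segment.
#' @return Scalar feature value.
#' @export
lmav <- function(x) {
  m <- mean(abs(x))
  if (!length(x) || m <= 0) {
    stop_gaitdx("LMAV undefined on an all-zero segment",
                class = "gaitdx_undefined_feature")
  }
  log(m)
}

#' Nonlinear scaled value
#'
#' The v-order amplitude statistic `(mean(|x|^v))^(1/v)`, default `v = 3`.
#'
#' @param x Numeric segment.
#' @param v Order of the statistic.
#' @return Scalar feature value.
#' @export
nsv <- function(x, v = 3) {
  mean(abs(x)^v)^(1 / v)
}

#' Waveform length
#'
#' Total variation of the segment: `sum(|diff(x)|)`.
#'
#' @param x Numeric segment of length at least 2.
#' @return Scalar feature value.
#' @export
waveform_length <- function(x) {
  if (length(x) < 2) {
    stop_gaitdx("waveform length needs at least 2 samples",
                class = "gaitdx_segment_too_short")
  }
  sum(abs(diff(x)))
}

#' Threshold-count features: WAMP, ZC, SSC
#'
#' Wilson amplitude (steps of `|diff|` at or above `theta_wamp`), zero
#' crossings (sign changes whose jump is at least `theta_zc`), and slope sign
#' changes (local extrema whose larger neighbouring step is at least
#' `theta_ssc`).
#'
#' @param x Numeric segment of length at least 3.
#' @param theta_wamp,theta_zc,theta_ssc Nonnegative thresholds. Defaults are
#'   tuned for mean-normalized signals.
#' @return Named numeric vector `c(WAMP=, ZC=, SSC=)`.
#' @export
threshold_counts <- function(x, theta_wamp = 0.05, theta_zc = 0,
                             theta_ssc = 0) {
  if (any(c(theta_wamp, theta_zc, theta_ssc) < 0)) {
    stop_gaitdx("thresholds must be nonnegative", class = "gaitdx_config_error")
  }
  if (length(x) < 3) {
    stop_gaitdx("threshold counts need at least 3 samples",
                class = "gaitdx_segment_too_short")
  }
  d <- diff(x)
  wamp <- sum(abs(d) >= theta_wamp)
  zc <- sum(x[-length(x)] * x[-1] < 0 & abs(d) >= theta_zc)
  i <- 2:(length(x) - 1)
  back <- x[i] - x[i - 1]
  fwd <- x[i] - x[i + 1]
  ssc <- sum(back * fwd > 0 & pmax(abs(back), abs(fwd)) >= theta_ssc)
  c(WAMP = wamp, ZC = zc, SSC = ssc)
}

#' Hjorth parameters: mobility and complexity
#'
#' `MOB = sqrt(var(diff(x)) / var(x))`; `COM = MOB(diff(x)) / MOB(x)`.
#' Degenerate variances (constant segment or constant first difference) map
#' to 0 by convention.
#'
#' @param x Numeric segment of length at least 3.
#' @return Named numeric vector `c(MOB=, COM=)`.
#' @export
hjorth_params <- function(x) {
  mob <- function(z) {
    if (length(z) < 2) return(0)
    v <- stats::var(z)
    if (!is.finite(v) || v <= 0) return(0)
    vd <- stats::var(diff(z))
    sqrt(vd / v)
  }
  m <- mob(x)
  com <- if (m > 0) mob(diff(x)) / m else 0
  c(MOB = m, COM = com)
}

#' Sample skewness (population estimator)
#'
#' Third standardized central moment with the biased `1/N` normalization;
#' 0 by convention for zero-variance segments.
#'
#' @param x Numeric segment.
#' @return Scalar skewness.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

#' Autoregressive coefficients (Yule-Walker)
#'
#' Fits an AR(`order`) model by the Yule-Walker equations (Levinson-Durbin,
#' via [stats::ar()]), with the sign convention
#' `x_t ~ sum_k AR_k * x_{t-k}`.
#'
#' @param x Numeric segment with positive variance and length > 4 * order.
#' @param order Model order (default 4).
#' @return Named numeric vector `AR1`..`AR<order>`.
#' @export
ar_coefficients <- function(x, order = 4) {
  if (length(x) <= 4 * order) {
    stop_gaitdx("segment too short for AR(", order, ") estimation",
                class = "gaitdx_segment_too_short")
  }
  if (stats::var(x) <= 0) {
    stop_gaitdx("AR coefficients undefined on a zero-variance segment",
                class = "gaitdx_undefined_feature")
  }
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker")
  stats::setNames(as.numeric(fit$ar), paste0("AR", seq_len(order)))
}

#' Time-domain surrogates of the even spectral moments
#'
#' `m0 = sum(x^2)`, `m2 = sum(diff(x)^2)`, `m4 = sum(diff^2(x)^2)`,
#' `m6 = sum(diff^3(x)^2)` -- by Parseval these are the 0th/2nd/4th/6th-order
#' spectral moments up to frequency scaling.
#'
#' @param x Numeric segment of length at least 4.
#' @return Named numeric vector `c(m0=, m2=, m4=, m6=)`.
#' @export
td_spectral_moments <- function(x) {
  d1 <- diff(x)
  d2 <- diff(d1)
  d3 <- diff(d2)
  c(m0 = sum(x^2), m2 = sum(d1^2), m4 = sum(d2^2), m6 = sum(d3^2))
}

#' Amplitude-change features
#'
#' `AC1 = mean(|diff(x)|)`, `AC2 = mean(|diff(x, differences = 2)|)`.
#'
#' @param x Numeric segment of length at least 3.
#' @return Named numeric vector `c(AC1=, AC2=)`.
#' @export
amplitude_changes <- function(x) {
  c(AC1 = mean(abs(diff(x))), AC2 = mean(abs(diff(x, differences = 2))))
}

#' The 19-feature time-domain EMG vector
#'
#' Computes the full per-muscle feature vector in the fixed canonical order
#' LMAV, NSV, WL, WAMP, SSC, ZC, MOB, COM, SKW, AR1--AR4, m0, m2, m4, m6,
#' AC1, AC2, with names qualified as `<channel>__<feature>`.
#'
#' @param x Preprocessed, scale-normalized segment.
#' @param channel Channel name used to qualify feature names.
#' @param theta_wamp,theta_zc,theta_ssc Thresholds for [threshold_counts()].
#' @param strict If `TRUE` (default) a zero-variance segment raises an
#'   undefined-feature error from the AR stage; with `FALSE` (used by the
#'   GRF time-domain bank, whose contract covers constant segments) the AR
#'   coefficients fall back to 0.
#' @return Named numeric vector of length 19; any non-finite value raises an
#'   error naming the channel.
#' @export
emg_feature_vector <- function(x, channel = "EMG", theta_wamp = 0.05,
                               theta_zc = 0, theta_ssc = 0, strict = TRUE) {
  tc <- threshold_counts(x, theta_wamp, theta_zc, theta_ssc)
  ar <- if (!strict && stats::var(x) <= 0) {
    stats::setNames(numeric(4), paste0("AR", 1:4))
  } else {
    ar_coefficients(x)
  }
  v <- c(
    LMAV = lmav(x),
    NSV = nsv(x),
    WL = waveform_length(x),
    tc,
    hjorth_params(x),
    SKW = sample_skewness(x),
    ar,
    td_spectral_moments(x),
    amplitude_changes(x)
  )
  v <- v[emg_feature_names()]
  if (any(!is.finite(v))) {
    stop_gaitdx("non-finite EMG feature(s) on channel ", channel, ": ",
                paste(emg_feature_names()[!is.finite(v)], collapse = ", "),
                class = "gaitdx_undefined_feature")
  }
  stats::setNames(as.numeric(v), paste0(channel, "__", emg_feature_names()))
}
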