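# Signal conditioning: zero-phase Butterworth filtering, mains-notch removal,
# vGRF stance segmentation, quality screening and mean normalization.

# ---- filter design -------------------------------------------------------

# Second-order IIR notch (RBJ cookbook), centre `f0` Hz, quality factor `q`.
notch_biquad <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Filter specifications used by the preprocessing stage
#'
#' Builds the filter cascade applied to a channel: a fourth-order Butterworth
#' band-pass 25--499 Hz plus 60 Hz notch filters at every harmonic below
#' Nyquist for EMG, or a fourth-order Butterworth low-pass at 100 Hz for GRF.
#' All filters are applied zero-phase (forward-backward), so the effective
#' attenuation is the squared magnitude of the design.
#'
#' @param kind `"emg"` or `"grf"`.
#' @param fs Sampling rate in Hz.
#' @param band Band-pass corners in Hz (EMG).
#' @param lowpass Low-pass corner in Hz (GRF).
#' @param notch_base Mains frequency in Hz; harmonics up to Nyquist are notched.
#' @param notch_q Notch quality factor.
#' @return An object of class `filter_spec`: a list of `(b, a)` filter
#'   coefficient pairs plus metadata.
#' @export
filter_spec <- function(kind = c("emg", "grf"), fs,
                        band = c(25, 499), lowpass = 100,
                        notch_base = 60, notch_q = 30) {
  kind <- match.arg(kind)
  key <- paste(kind, fs, paste(band, collapse = "-"), lowpass, notch_base,
               notch_q, sep = "|")
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  nyq <- fs / 2
  filters <- list()
  if (kind == "emg") {
    if (nyq <= band[2]) {
      stop_gaitdx("sampling rate ", fs, " Hz too low for the ", band[2],
                  " Hz band-pass corner", class = "gaitdx_config_error")
    }
    bp <- signal::butter(4, band / nyq, type = "pass")
    filters <- c(filters, list(list(b = bp$b, a = bp$a)))
    harmonics <- seq(notch_base, nyq - 1e-9, by = notch_base)
    harmonics <- harmonics[harmonics < nyq]
    for (f0 in harmonics) {
      filters <- c(filters, list(notch_biquad(f0, fs, notch_q)))
    }
  } else {
    if (fs <= 200) {
      stop_gaitdx("sampling rate ", fs, " Hz too low for the ", lowpass,
                  " Hz low-pass corner", class = "gaitdx_config_error")
    }
    lp <- signal::butter(4, lowpass / nyq, type = "low")
    filters <- list(list(b = lp$b, a = lp$a))
  }
  out <- structure(list(kind = kind, fs = fs, filters = filters),
                   class = "filter_spec")
  .filter_cache[[key]] <- out
  out
}

# Squared-magnitude frequency response of the cascade at angular freqs `w`.
cascade_mag2 <- function(spec, w) {
  m <- rep(1, length(w))
  for (f in spec$filters) {
    e <- exp(-1i * outer(seq_along(f$b) - 1, w))
    num <- as.vector(f$b %*% e)
    e <- exp(-1i * outer(seq_along(f$a) - 1, w))
    den <- as.vector(f$a %*% e)
    m <- m * (Mod(num) / Mod(den))^2
  }
  m
}

#' Zero-phase application of a filter cascade
#'
#' Applies the forward-backward (squared-magnitude, zero-phase) response of a
#' [filter_spec()] cascade. The signal is mirror-extended to twice its length
#' and filtered circularly in the frequency domain, which realizes the
#' filtfilt operator without boundary transients; the operation commutes
#' exactly with time reversal.
#'
#' @param x Numeric signal.
#' @param spec A `filter_spec`.
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_apply <- function(x, spec) {
  n <- length(x)
  if (n < 13) {
    stop_gaitdx("signal too short to filter (", n, " samples)",
                class = "gaitdx_segment_too_short")
  }
  z <- c(x, rev(x))
  nn <- 2L * n
  w <- 2 * pi * (seq_len(nn) - 1) / nn
  m <- cascade_mag2(spec, w)
  y <- Re(stats::fft(stats::fft(z) * m, inverse = TRUE)) / nn
  y[seq_len(n)]
}

# ---- channel preprocessing ----------------------------------------------

#' Preprocess a raw EMG channel
#'
#' Full-wave rectification followed by a zero-phase fourth-order Butterworth
#' band-pass (25--499 Hz) and zero-phase 60 Hz notch filters at every harmonic
#' below Nyquist, in that order.
#'
#' @param raw Raw EMG samples.
#' @param fs Sampling rate in Hz (must exceed twice the 499 Hz corner).
#' @param spec Optional pre-built [filter_spec()]; rebuilt from `fs` otherwise.
#' @return Conditioned signal, same length as `raw`.
#' @export
preprocess_emg <- function(raw, fs, spec = NULL) {
  if (is.null(spec)) spec <- filter_spec("emg", fs)
  zero_phase_apply(abs(raw), spec)
}

#' Preprocess a raw GRF channel
#'
#' Zero-phase fourth-order Butterworth low-pass at 100 Hz.
#'
#' @inheritParams preprocess_emg
#' @return Conditioned signal, same length as `raw`.
#' @export
preprocess_grf <- function(raw, fs, spec = NULL) {
  if (is.null(spec)) spec <- filter_spec("grf", fs)
  zero_phase_apply(raw, spec)
}

# ---- segmentation and screening -----------------------------------------

#' Segment gait cycles from the vertical ground reaction force
#'
#' Stance intervals are the runs where the (preprocessed) vGRF stays above
#' `threshold_frac` of its per-recording maximum for at least `min_high`
#' seconds. Intervals are 0-based half-open `[start, end)` sample spans,
#' disjoint and ordered.
#'
#' @param vgrf Preprocessed vertical GRF samples.
#' @param fs Sampling rate in Hz.
#' @param threshold_frac Fraction of the vGRF maximum used as the contact
#'   threshold (default 0.05).
#' @param min_high Minimum sustained supra-threshold duration in seconds.
#' @return Data frame with integer columns `start`, `end` (0-based,
#'   half-open); zero rows if nothing crosses the threshold.
#' @export
segment_gait_cycles <- function(vgrf, fs, threshold_frac = 0.05,
                                min_high = 0.05) {
  check_fraction(threshold_frac, "threshold_frac", open_hi = TRUE)
  if (threshold_frac <= 0) {
    stop_gaitdx("threshold_frac must be positive", class = "gaitdx_config_error")
  }
  empty <- data.frame(start = integer(0), end = integer(0))
  mx <- max(vgrf)
  if (!is.finite(mx) || mx <= 0) return(empty)
  above <- vgrf > threshold_frac * mx
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= max(1L, round(min_high * fs))
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Quality screen for a segmented stance interval
#'
#' Accepts an interval iff its duration lies inside `[min_dur, max_dur]`
#' seconds and (when the segment samples are supplied) its peak amplitude is
#' positive. A stand-in for the semi-manual screening a human rater would do.
#'
#' @param interval One-row data frame (or list) with `start`, `end` (0-based,
#'   half-open samples).
#' @param fs Sampling rate in Hz.
#' @param x Optional segment samples for the peak-amplitude check.
#' @param min_dur,max_dur Accepted duration window in seconds.
#' @return List with logical `accept` and character `reason` ("ok",
#'   "too short", "too long" or "no positive peak").
#' @export
quality_screen <- function(interval, fs, x = NULL,
                           min_dur = 0.3, max_dur = 1.5) {
  dur <- (interval$end - interval$start) / fs
  if (dur < min_dur) return(list(accept = FALSE, reason = "too short"))
  if (dur > max_dur) return(list(accept = FALSE, reason = "too long"))
  if (!is.null(x) && max(x) <= 0) {
    return(list(accept = FALSE, reason = "no positive peak"))
  }
  list(accept = TRUE, reason = "ok")
}

#' Normalize a segment by its mean
#'
#' Divides by the segment mean so the result has mean exactly 1. Intended for
#' strictly positive channels (the vertical GRF); zero-mean signals raise a
#' normalization error naming the channel.
#'
#' @param x Segment samples.
#' @param channel Channel name used in error messages.
#' @return `x / mean(x)`.
#' @export
normalize_by_mean <- function(x, channel = "signal") {
  m <- mean(x)
  if (!is.finite(m) || abs(m) < 1e-12 * max(1, max(abs(x)))) {
    stop_gaitdx("cannot mean-normalize channel ", channel,
                ": segment mean is zero", class = "gaitdx_normalization_error")
  }
  x / m
}

#' Scale-normalize a segment
#'
#' `method = "mean"` is [normalize_by_mean()]. `method = "mean_abs"` divides
#' by the mean absolute value, which is the well-posed analogue for zero-mean
#' channels (band-passed EMG, shear GRF components): it removes amplitude
#' scale while preserving sign structure.
#'
#' @param x Segment samples.
#' @param method `"mean"` or `"mean_abs"`.
#' @param channel Channel name used in error messages.
#' @return Normalized segment.
#' @export
normalize_segment <- function(x, method = c("mean", "mean_abs"),
                              channel = "signal") {
  method <- match.arg(method)
  if (method == "mean") return(normalize_by_mean(x, channel))
  m <- mean(abs(x))
  if (!is.finite(m) || m < 1e-12 * max(1, max(abs(x)))) {
    stop_gaitdx("cannot normalize channel ", channel,
                ": segment is all zero", class = "gaitdx_normalization_error")
  }
  x / m
}

# Normalization method used by the pipeline for each channel.
channel_norm_method <- function(channel) {
  if (channel == "GRFz") "mean" else "mean_abs"
}

#' Preprocess one recording into normalized stance segments
#'
#' Runs the full conditioning chain of the pipeline on a single recording:
#' the vertical GRF is low-pass filtered and segmented into stance intervals,
#' each interval is quality-screened, and every requested channel is
#' filtered (EMG: rectify + band-pass + notch; GRF: low-pass), cut to the
#' interval and scale-normalized (vGRF by its mean; EMG and shear GRF by
#' their mean absolute value).
#'
#' @param rec A `gait_recording` (see [generate_cohort()]).
#' @param channels Channels to extract; default all six.
#' @param threshold_frac,min_high Passed to [segment_gait_cycles()].
#' @param min_dur,max_dur Passed to [quality_screen()].
#' @return List with `intervals` (data frame `start`, `end`, `accepted`,
#'   `reason`) and `segments`: for each accepted interval, a named list of
#'   normalized per-channel segments.
#' @export
preprocess_recording <- function(rec, channels = gait_channels(),
                                 threshold_frac = 0.05, min_high = 0.05,
                                 min_dur = 0.3, max_dur = 1.5) {
  stopifnot(inherits(rec, "gait_recording"))
  bad <- setdiff(channels, gait_channels())
  if (length(bad)) {
    stop_gaitdx("unknown channel(s): ", paste(bad, collapse = ", "),
                class = "gaitdx_config_error")
  }
  fs <- rec$fs
  grf_f <- filter_spec("grf", fs)
  vgrf <- zero_phase_apply(rec$channels[["GRFz"]], grf_f)
  iv <- segment_gait_cycles(vgrf, fs, threshold_frac, min_high)
  if (nrow(iv) == 0L) {
    return(list(intervals = cbind(iv, accepted = logical(0), reason = character(0)),
                segments = list()))
  }
  screened <- lapply(seq_len(nrow(iv)), function(i) {
    idx <- (iv$start[i] + 1L):iv$end[i]
    quality_screen(iv[i, ], fs, vgrf[idx], min_dur, max_dur)
  })
  iv$accepted <- vapply(screened, `[[`, logical(1), "accept")
  iv$reason <- vapply(screened, `[[`, character(1), "reason")

  emg_f <- if (any(is_emg_channel(channels))) filter_spec("emg", fs) else NULL
  filtered <- lapply(stats::setNames(channels, channels), function(ch) {
    if (is_emg_channel(ch)) {
      preprocess_emg(rec$channels[[ch]], fs, emg_f)
    } else if (ch == "GRFz") {
      vgrf
    } else {
      zero_phase_apply(rec$channels[[ch]], grf_f)
    }
  })
  segs <- lapply(which(iv$accepted), function(i) {
    idx <- (iv$start[i] + 1L):iv$end[i]
    lapply(stats::setNames(channels, channels), function(ch) {
      normalize_segment(filtered[[ch]][idx], channel_norm_method(ch),
                        channel = ch)
    })
  })
  list(intervals = iv, segments = segs)
}
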