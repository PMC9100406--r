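# GRF feature bank: 50 time-domain + 24 frequency-domain + 121 wavelet
# (time-frequency) features per GRF-component segment = 195 in total.
# The registries below are the single source of truth for names and
# formulas; every extractor just walks its registry.

# ---- time-domain registry (19 shared EMG features + 31 shape statistics) ---

# Principal peaks: the segment is split at its midpoint; PK1/PK2 are the
# maxima of each half and TPK1/TPK2 their positions as fractions of the
# segment length. Total functions: defined for every finite segment.
principal_peaks <- function(x) {
  n <- length(x)
  half <- max(1L, n %/% 2L)
  i1 <- which.max(x[seq_len(half)])
  i2 <- half + which.max(x[(half + 1L):n])
  c(pk1 = x[i1], pk2 = x[i2],
    tpk1 = (i1 - 1) / (n - 1), tpk2 = (i2 - 1) / (n - 1))
}

local_maxima_count <- function(x, frac = 0.25) {
  n <- length(x)
  if (n < 3) return(0)
  i <- 2:(n - 1)
  cand <- x[i] > x[i - 1] & x[i] >= x[i + 1]
  lev <- min(x) + frac * (max(x) - min(x))
  sum(cand & x[i] > lev)
}

safe_div <- function(a, b) if (abs(b) < 1e-12) 0 else a / b

grf_td_registry <- function() {
  list(
    MAX = function(x, n) max(x),
    MIN = function(x, n) min(x),
    PTP = function(x, n) max(x) - min(x),
    TMAX = function(x, n) (which.max(x) - 1) / (n - 1),
    TMIN = function(x, n) (which.min(x) - 1) / (n - 1),
    RMS = function(x, n) sqrt(mean(x^2)),
    SD = function(x, n) stats::sd(x),
    VAR = function(x, n) stats::var(x),
    KURT = function(x, n) {
      s2 <- mean((x - mean(x))^2)
      if (s2 <= 0) 0 else mean((x - mean(x))^4) / s2^2
    },
    IQR = function(x, n) stats::IQR(x),
    P5 = function(x, n) stats::quantile(x, 0.05, names = FALSE),
    P25 = function(x, n) stats::quantile(x, 0.25, names = FALSE),
    P75 = function(x, n) stats::quantile(x, 0.75, names = FALSE),
    P95 = function(x, n) stats::quantile(x, 0.95, names = FALSE),
    MED = function(x, n) stats::median(x),
    MAV = function(x, n) mean(abs(x)),
    CREST = function(x, n) safe_div(max(abs(x)), sqrt(mean(x^2))),
    SHAPE = function(x, n) safe_div(sqrt(mean(x^2)), mean(abs(x))),
    IMPULSE = function(x, n) safe_div(max(abs(x)), mean(abs(x))),
    PK1 = function(x, n) principal_peaks(x)[["pk1"]],
    PK2 = function(x, n) principal_peaks(x)[["pk2"]],
    TPK1 = function(x, n) principal_peaks(x)[["tpk1"]],
    TPK2 = function(x, n) principal_peaks(x)[["tpk2"]],
    PKRATIO = function(x, n) {
      p <- principal_peaks(x)
      safe_div(p[["pk2"]], p[["pk1"]])
    },
    NPEAKS = function(x, n) local_maxima_count(x),
    MSLOPE = function(x, n) mean(diff(x)),
    MAXSLOPE = function(x, n) max(diff(x)),
    MINSLOPE = function(x, n) min(diff(x)),
    SDSLOPE = function(x, n) stats::sd(diff(x)),
    MAD = function(x, n) stats::mad(x),
    POSFRAC = function(x, n) mean(x > mean(x))
  )
}

#' Time-domain GRF features (50 per component)
#'
#' The 19 time-domain EMG features plus 31 registered amplitude, shape and
#' timing statistics (extrema, principal-peak heights and times as segment
#' fractions, dispersion and percentile statistics, slope statistics, crest /
#' shape / impulse factors). Peak times are dimensionless fractions so
#' variable-length stances are comparable.
#'
#' @param x Accepted, scale-normalized segment.
#' @param channel Channel name used to qualify feature names.
#' @return Named numeric vector of length 50.
#' @export
grf_td_features <- function(x, channel = "GRF") {
  base <- emg_feature_vector(x, channel, strict = FALSE)
  reg <- grf_td_registry()
  n <- length(x)
  extra <- vapply(reg, function(f) f(x, n), numeric(1))
  v <- c(base, stats::setNames(extra, paste0(channel, "__", names(reg))))
  if (any(!is.finite(v))) {
    stop_gaitdx("non-finite TD feature(s) on channel ", channel,
                class = "gaitdx_undefined_feature")
  }
  v
}

# ---- frequency-domain registry ------------------------------------------

# One-sided Hann-window periodogram, DC bin excluded (mean-normalized
# segments carry their scale in the DC bin).
grf_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- (x - mean(x)) * w
  nf <- n %/% 2L
  X <- stats::fft(xw)[seq_len(nf + 1L)]
  p <- Mod(X)^2 / sum(w^2)
  f <- (0:nf) * fs / n
  list(f = f[-1], p = p[-1])
}

grf_fd_names <- function() {
  c("F_PEAK", "F_MEAN", "F_MEDIAN", "F_SD", "F_SKEW", "F_KURT",
    "SENTROPY", "FLATNESS", "P_TOTAL", "LOG_P_TOTAL",
    "BAND_0_10", "BAND_10_25", "BAND_25_50", "BAND_50_100",
    "BAND_100_200", "BAND_200_PLUS", "LF_HF_RATIO", "PEAK_FRAC",
    "ROLLOFF25", "ROLLOFF75", "ROLLOFF90", "ROLLOFF95",
    "SPEC_SLOPE", "SPEC_CREST")
}

#' Frequency-domain GRF features (24 per component)
#'
#' Spectral statistics of the one-sided Hann-window periodogram (DC bin
#' excluded): peak/mean/median frequency, spectral spread, skewness and
#' kurtosis, normalized spectral entropy, flatness, total power, band-power
#' fractions over registered bands, low/high-frequency power ratio, rolloff
#' frequencies, spectral slope and crest.
#'
#' @param x Segment of length at least 64.
#' @param fs Sampling rate in Hz.
#' @param channel Channel name used to qualify feature names.
#' @return Named numeric vector of length 24.
#' @export
grf_fd_features <- function(x, fs, channel = "GRF") {
  if (length(x) < 64) {
    stop_gaitdx("FD features need at least 64 samples",
                class = "gaitdx_segment_too_short")
  }
  pg <- grf_periodogram(x, fs)
  f <- pg$f
  p <- pg$p
  ptot <- sum(p)
  pr <- if (ptot > 0) p / ptot else rep(1 / length(p), length(p))
  cdf <- cumsum(pr)
  rolloff <- function(q) f[which(cdf >= q)[1]]
  fmean <- sum(f * pr)
  fsd <- sqrt(sum((f - fmean)^2 * pr))
  band <- function(lo, hi) sum(pr[f >= lo & f < hi])
  ent <- -sum(ifelse(pr > 0, pr * log(pr), 0)) / log(length(pr))
  v <- c(
    F_PEAK = f[which.max(p)],
    F_MEAN = fmean,
    F_MEDIAN = rolloff(0.5),
    F_SD = fsd,
    F_SKEW = if (fsd > 0) sum(((f - fmean) / fsd)^3 * pr) else 0,
    F_KURT = if (fsd > 0) sum(((f - fmean) / fsd)^4 * pr) else 0,
    SENTROPY = ent,
    FLATNESS = if (ptot > 0) exp(mean(log(p + 1e-300))) / mean(p) else 0,
    P_TOTAL = ptot,
    LOG_P_TOTAL = log(ptot + 1e-300),
    BAND_0_10 = band(0, 10),
    BAND_10_25 = band(10, 25),
    BAND_25_50 = band(25, 50),
    BAND_50_100 = band(50, 100),
    BAND_100_200 = band(100, 200),
    BAND_200_PLUS = band(200, Inf),
    LF_HF_RATIO = safe_div(band(0, 50), band(50, Inf)),
    PEAK_FRAC = if (ptot > 0) max(p) / ptot else 0,
    ROLLOFF25 = rolloff(0.25),
    ROLLOFF75 = rolloff(0.75),
    ROLLOFF90 = rolloff(0.90),
    ROLLOFF95 = rolloff(0.95),
    SPEC_SLOPE = unname(stats::coef(stats::lm.fit(cbind(1, f),
                                                  log(p + 1e-300)))[2]),
    SPEC_CREST = safe_div(max(p), mean(p))
  )
  if (any(!is.finite(v))) {
    stop_gaitdx("non-finite FD feature(s) on channel ", channel,
                class = "gaitdx_undefined_feature")
  }
  stats::setNames(as.numeric(v), paste0(channel, "__FD_", grf_fd_names()))
}

# ---- time-frequency (wavelet) registry ----------------------------------

tfd_band_feature_names <- function() {
  c("ENERGY", "LOGE", "MEANABS", "SD", "ENTROPY", "MAXABS", "WL", "ZC", "RELE")
}

tfd_band_features <- function(coef, tot_energy) {
  e <- sum(coef^2)
  p <- if (e > 0) coef^2 / e else numeric(0)
  c(
    ENERGY = e,
    LOGE = log(e + 1e-300),
    MEANABS = mean(abs(coef)),
    SD = if (length(coef) > 1) stats::sd(coef) else 0,
    ENTROPY = if (e > 0) -sum(ifelse(p > 0, p * log(p), 0)) else 0,
    MAXABS = max(abs(coef)),
    WL = if (length(coef) > 1) sum(abs(diff(coef))) else 0,
    ZC = sum(coef[-length(coef)] * coef[-1] < 0),
    RELE = safe_div(e, tot_energy)
  )
}

#' Time-frequency GRF features from a wavelet decomposition (121)
#'
#' Nine statistics (energy, log-energy, mean absolute value, SD, coefficient
#' entropy, max absolute value, waveform length, zero crossings, relative
#' energy) for each of the 13 named sub-bands, plus four global features:
#' total energy, detail/approximation energy ratio, entropy of the band
#' relative-energy distribution, and the index of the maximum-energy band.
#' Relative energies are fractions of the orthogonal-partition energy
#' (`D1`--`D8` + `cA8`), so those nine fractions sum to 1.
#'
#' @param dec A `wavelet_decomposition` from [dwt_subbands()].
#' @param channel Channel name used to qualify feature names.
#' @return Named numeric vector of length 121.
#' @export
grf_tfd_features <- function(dec, channel = "GRF") {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  bands <- dec$bands
  ortho <- c(paste0("D", seq_len(dec$levels)), "cA8")
  tot <- sum(vapply(bands[ortho], function(b) sum(b^2), numeric(1)))
  per_band <- unlist(lapply(names(bands), function(nm) {
    stats::setNames(tfd_band_features(bands[[nm]], tot),
                    paste0(channel, "__TFD_", nm, "_", tfd_band_feature_names()))
  }))
  energies <- vapply(bands, function(b) sum(b^2), numeric(1))
  rel <- energies / sum(energies)
  det_e <- sum(energies[paste0("D", seq_len(dec$levels))])
  glob <- stats::setNames(
    c(tot,
      safe_div(det_e, energies[["cA8"]]),
      -sum(ifelse(rel > 0, rel * log(rel), 0)),
      which.max(energies)),
    paste0(channel, "__TFD_", c("TOT_ENERGY", "DETAIL_APPROX_RATIO",
                                "BAND_ENTROPY", "MAX_BAND")))
  v <- c(per_band, glob)
  if (any(!is.finite(v))) {
    stop_gaitdx("non-finite TFD feature(s) on channel ", channel,
                class = "gaitdx_undefined_feature")
  }
  v
}

#' Full 195-feature GRF vector for one component segment
#'
#' Concatenation of the 50 time-domain, 24 frequency-domain and 121
#' time-frequency features, all names qualified by the channel.
#'
#' @param x Accepted, scale-normalized segment.
#' @param fs Sampling rate in Hz.
#' @param channel Channel name (e.g. `"GRFz"`).
#' @param wavelet Wavelet used for the time-frequency bank.
#' @param sets Which feature families to compute (subset of
#'   `c("td", "fd", "tfd")`); default all three.
#' @return Named numeric vector (length 195 with all sets).
#' @export
grf_feature_vector <- function(x, fs, channel = "GRF", wavelet = "db4",
                               sets = c("td", "fd", "tfd")) {
  sets <- match.arg(sets, several.ok = TRUE)
  out <- numeric(0)
  if ("td" %in% sets) out <- c(out, grf_td_features(x, channel))
  if ("fd" %in% sets) out <- c(out, grf_fd_features(x, fs, channel))
  if ("tfd" %in% sets) {
    out <- c(out, grf_tfd_features(dwt_subbands(x, wavelet), channel))
  }
  out
}
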