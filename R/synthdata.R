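# Synthetic gait cohort generator. Emulates the statistical structure the
# analysis assumes: three classes (control, DN, DFU) with a class-dependent
# gait-timing delay (later muscle-activation peak and later vGRF push-off
# hump) and a reduced second vertical-GRF peak in the diseased classes, plus
# between-subject random effects that make subject-wise cross-validation
# meaningfully harder than record-wise.

#' Configuration of a synthetic gait cohort
#'
#' Defaults emulate the 21-subject cohort of the study conditions: control
#' n = 6, DN n = 6, DFU n = 9, 20 gait cycles per subject at 1000 Hz, with a
#' 60 ms (DN) / 100 ms (DFU) activation-peak delay and a 15% reduction of the
#' second vertical-GRF peak in the diseased classes.
#'
#' @param n_control,n_dn,n_dfu Subjects per class.
#' @param cycles_per_subject Gait cycles recorded per subject.
#' @param fs Sampling rate (Hz).
#' @param cycle_duration Stance duration in seconds.
#' @param dn_peak_delay,dfu_peak_delay Class activation-peak delays in
#'   seconds (`dfu_peak_delay >= dn_peak_delay`).
#' @param second_peak_reduction Fraction in `[0, 1)` by which the second
#'   vertical-GRF hump of DN/DFU subjects is reduced.
#' @param noise_sd Additive noise amplitude as a fraction of each channel's
#'   nominal amplitude.
#' @param subject_sd Between-subject random-effect scale: SD in seconds of a
#'   subject-level gait-timing shift shared by all of that subject's cycles.
#'   Subjects also carry a multiplicative log-normal amplitude factor
#'   (sdlog 0.1).
#' @param seed Integer seed; the cohort is bit-reproducible given
#'   `(config, seed)`.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 6, n_dn = 6, n_dfu = 9,
                          cycles_per_subject = 20, fs = 1000,
                          cycle_duration = 0.8,
                          dn_peak_delay = 0.06, dfu_peak_delay = 0.10,
                          second_peak_reduction = 0.15,
                          noise_sd = 0.05, subject_sd = 0.01,
                          seed = 1L) {
  cfg <- list(
    n_control = check_count(n_control, "n_control"),
    n_dn = check_count(n_dn, "n_dn"),
    n_dfu = check_count(n_dfu, "n_dfu"),
    cycles_per_subject = check_count(cycles_per_subject, "cycles_per_subject"),
    fs = fs, cycle_duration = cycle_duration,
    dn_peak_delay = dn_peak_delay, dfu_peak_delay = dfu_peak_delay,
    second_peak_reduction = check_fraction(second_peak_reduction,
                                           "second_peak_reduction",
                                           open_hi = TRUE),
    noise_sd = noise_sd, subject_sd = subject_sd,
    seed = as.integer(seed)
  )
  if (!is.numeric(fs) || fs <= 0 || !is.numeric(cycle_duration) ||
      cycle_duration <= 0) {
    stop_gaitdx("fs and cycle_duration must be positive",
                class = "gaitdx_config_error")
  }
  if (dn_peak_delay < 0 || dfu_peak_delay < dn_peak_delay) {
    stop_gaitdx("need 0 <= dn_peak_delay <= dfu_peak_delay",
                class = "gaitdx_config_error")
  }
  if (noise_sd < 0 || subject_sd < 0) {
    stop_gaitdx("noise_sd and subject_sd must be nonnegative",
                class = "gaitdx_config_error")
  }
  structure(cfg, class = "cohort_config")
}

class_delay <- function(label, config) {
  switch(label, control = 0, DN = config$dn_peak_delay,
         DFU = config$dfu_peak_delay,
         stop_gaitdx("unknown class label: ", label,
                     class = "gaitdx_config_error"))
}

cycle_time_grid <- function(config) {
  n <- round(config$cycle_duration * config$fs)
  seq(0, config$cycle_duration, length.out = n)
}

#' Synthesize one EMG gait-cycle channel
#'
#' A zero-mean broadband carrier (white noise band-passed 25--499 Hz, unit
#' SD) modulated by a nonnegative Gaussian activation envelope centred at 40%
#' of the cycle for controls, shifted later by the class delay plus the
#' subject gait-timing effect. Additive white noise at `noise_sd`. Draws from
#' the current RNG stream; [generate_cohort()] seeds it.
#'
#' @param label Class label (`"control"`, `"DN"`, `"DFU"`).
#' @param config A [cohort_config()].
#' @param subject_effect Subject gait-timing shift in seconds.
#' @param amp Subject amplitude factor.
#' @return Numeric vector of `round(cycle_duration * fs)` samples.
#' @export
synth_emg_cycle <- function(label, config, subject_effect = 0, amp = 1) {
  t <- cycle_time_grid(config)
  n <- length(t)
  cd <- config$cycle_duration
  centre <- 0.4 * cd + class_delay(label, config) + subject_effect
  env <- exp(-0.5 * ((t - centre) / (0.08 * cd))^2)
  spec <- filter_spec("emg", config$fs)
  carrier <- zero_phase_apply(stats::rnorm(n), spec)
  carrier <- carrier / stats::sd(carrier)
  amp * (env * carrier + config$noise_sd * stats::rnorm(n))
}

# Gaussian hump multiplied by the stance taper, rescaled so its actual
# maximum equals `h` (the taper would otherwise shift and shrink the peak).
taper_hump <- function(t, cd, c0, s, h, taper) {
  shape <- exp(-0.5 * ((t - c0) / s)^2) * taper
  mx <- max(shape)
  if (mx <= 0) return(shape)
  (h / mx) * shape
}

#' Synthesize one gait-cycle of 3-D ground reaction forces
#'
#' `GRFz` is the classic M-shaped (double-hump) stance curve, zero at both
#' ends, with the second (push-off) hump scaled by
#' `1 - second_peak_reduction` for DN/DFU and shifted later by the class
#' delay plus the subject gait-timing effect (delayed plantar-flexor
#' activation delays propulsion). `GRFy` is the antisymmetric
#' braking/propulsion shear (propulsion hump shares the timing shift);
#' `GRFx` is a small mediolateral hump. Additive noise at `noise_sd` of each
#' channel's nominal amplitude.
#'
#' @inheritParams synth_emg_cycle
#' @return Named list of numeric vectors `GRFx`, `GRFy`, `GRFz`.
#' @export
synth_grf_cycle <- function(label, config, subject_effect = 0, amp = 1) {
  t <- cycle_time_grid(config)
  n <- length(t)
  cd <- config$cycle_duration
  tau <- class_delay(label, config) + subject_effect
  red <- if (label == "control") 0 else config$second_peak_reduction
  taper <- sin(pi * t / cd)^0.25
  taper[c(1L, n)] <- 0  # exact zero at foot contact / toe-off

  c1 <- 0.27 * cd
  c2 <- 0.72 * cd + tau
  z <- taper_hump(t, cd, c1, 0.13 * cd, 1, taper) +
    taper_hump(t, cd, c2, 0.13 * cd, 1 - red, taper)
  y <- -taper_hump(t, cd, 0.25 * cd, 0.07 * cd, 0.15, taper) +
    taper_hump(t, cd, 0.70 * cd + tau, 0.07 * cd, 0.15, taper)
  x <- taper_hump(t, cd, 0.5 * cd, 0.18 * cd, 0.08, taper)

  noise <- function(scale) config$noise_sd * scale * stats::rnorm(n)
  list(GRFx = amp * (x + noise(0.08)),
       GRFy = amp * (y + noise(0.15)),
       GRFz = amp * (z + noise(1)))
}

#' Generate a synthetic gait cohort
#'
#' Returns one `gait_recording` per (subject, cycle): a list with
#' `subject_id`, `label`, `cycle`, `fs` and `channels` (named list of the six
#' equal-length channel signals GL, VL, TA, GRFx, GRFy, GRFz). Subject-level
#' random effects (gait-timing shift, amplitude factor) are drawn once per
#' subject and shared across that subject's cycles; the whole cohort is
#' deterministic given `(config, seed)`.
#'
#' @param config A [cohort_config()].
#' @return List of `gait_recording` objects, of length
#'   `(n_control + n_dn + n_dfu) * cycles_per_subject`, with class
#'   `gait_cohort`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- rep(gait_classes(),
                c(config$n_control, config$n_dn, config$n_dfu))
  ids <- unlist(lapply(gait_classes(), function(cl) {
    n <- switch(cl, control = config$n_control, DN = config$n_dn,
                DFU = config$n_dfu)
    sprintf("%s%02d", switch(cl, control = "C", DN = "DN", DFU = "DFU"),
            seq_len(n))
  }))
  recs <- with_seed(config$seed, {
    out <- list()
    for (s in seq_along(ids)) {
      time_eff <- stats::rnorm(1, 0, config$subject_sd)
      amp <- stats::rlnorm(1, 0, 0.1)
      for (cyc in seq_len(config$cycles_per_subject)) {
        emg <- lapply(stats::setNames(emg_channels(), emg_channels()),
                      function(ch) synth_emg_cycle(labels[s], config,
                                                   time_eff, amp))
        grf <- synth_grf_cycle(labels[s], config, time_eff, amp)
        out[[length(out) + 1L]] <- structure(
          list(subject_id = ids[s], label = labels[s], cycle = cyc,
               fs = config$fs, channels = c(emg, grf)),
          class = "gait_recording")
      }
    }
    out
  })
  structure(recs, class = "gait_cohort")
}

# ---- measurement helpers (used by tests and diagnostics) -----------------

#' Activation-envelope peak time of an EMG cycle
#'
#' Estimates the muscle-activation peak as the argmax of the low-pass
#' filtered (6 Hz, zero-phase) rectified signal.
#'
#' @param x EMG samples.
#' @param fs Sampling rate in Hz.
#' @return Peak time in seconds from cycle start.
#' @export
activation_peak_time <- function(x, fs) {
  lp <- signal::butter(4, 6 / (fs / 2), type = "low")
  spec <- structure(list(kind = "grf", fs = fs,
                         filters = list(list(b = lp$b, a = lp$a))),
                    class = "filter_spec")
  env <- zero_phase_apply(abs(x), spec)
  (which.max(env) - 1) / fs
}

#' Heights and times of the two principal vGRF humps
#'
#' Splits the (optionally smoothed) curve at its central minimum between the
#' two stance humps and reports the height and time of the maximum on each
#' side.
#'
#' @param z Vertical GRF samples for one stance.
#' @param fs Sampling rate in Hz.
#' @param smooth_hz Low-pass corner used to suppress noise before peak
#'   picking; `NULL` to skip smoothing.
#' @return Named list `first` and `second`, each `c(time=, height=)`.
#' @export
vgrf_peaks <- function(z, fs, smooth_hz = 20) {
  if (!is.null(smooth_hz)) {
    lp <- signal::butter(4, smooth_hz / (fs / 2), type = "low")
    spec <- structure(list(kind = "grf", fs = fs,
                           filters = list(list(b = lp$b, a = lp$a))),
                      class = "filter_spec")
    z <- zero_phase_apply(z, spec)
  }
  n <- length(z)
  mid <- round(0.35 * n):round(0.65 * n)
  split <- mid[which.min(z[mid])]
  i1 <- which.max(z[seq_len(split)])
  i2 <- split + which.max(z[(split + 1L):n]) - 1L
  list(first = c(time = (i1 - 1) / fs, height = z[i1]),
       second = c(time = (i2 - 1) / fs, height = z[i2]))
}

# ---- CSV external interface ---------------------------------------------

#' Write / read a cohort as CSV files plus a manifest
#'
#' Each recording becomes one CSV with columns `sample_index`, `GL`, `VL`,
#' `TA`, `GRFx`, `GRFy`, `GRFz`; `manifest.csv` lists
#' `(recording_file, subject_id, label, cycle, fs)`.
#'
#' @param cohort A `gait_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort`: the manifest data frame, invisibly.
#'   `read_cohort`: the reconstructed `gait_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(cohort, function(rec) {
    file <- sprintf("%s_cycle%03d.csv", rec$subject_id, rec$cycle)
    df <- data.frame(sample_index = seq_along(rec$channels[[1]]) - 1L,
                     rec$channels[gait_channels()])
    utils::write.csv(df, file.path(dir, file), row.names = FALSE)
    data.frame(recording_file = file, subject_id = rec$subject_id,
               label = rec$label, cycle = rec$cycle, fs = rec$fs)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    df <- utils::read.csv(file.path(dir, manifest$recording_file[i]))
    structure(list(subject_id = manifest$subject_id[i],
                   label = manifest$label[i],
                   cycle = manifest$cycle[i],
                   fs = manifest$fs[i],
                   channels = as.list(df[gait_channels()])),
              class = "gait_recording")
  })
  structure(recs, class = "gait_cohort")
}
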