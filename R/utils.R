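# Internal helpers shared across modules.

# Memoised filter designs (keyed by kind/fs/parameters); design is pure.
.filter_cache <- new.env(parent = emptyenv())

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_gaitdx <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "gaitdx_error")))
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)) {
    stop_gaitdx(name, " must be a positive integer", class = "gaitdx_config_error")
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  bad <- !is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo ||
    (if (open_hi) x >= hi else x > hi)
  if (bad) {
    stop_gaitdx(name, " must lie in [", lo, ", ", hi, if (open_hi) ")" else "]",
                class = "gaitdx_config_error")
  }
  as.numeric(x)
}

#' Gait channel names
#'
#' The three surface-EMG muscles and three ground-reaction-force components
#' handled by the pipeline.
#'
#' @return Character vectors of channel names.
#' @export
emg_channels <- function() c("GL", "VL", "TA")

#' @rdname emg_channels
#' @export
grf_channels <- function() c("GRFx", "GRFy", "GRFz")

#' @rdname emg_channels
#' @export
gait_channels <- function() c(emg_channels(), grf_channels())

#' Class labels of the cohort
#'
#' @return Character vector `c("control", "DN", "DFU")`.
#' @export
gait_classes <- function() c("control", "DN", "DFU")

is_emg_channel <- function(ch) ch %in% emg_channels()
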