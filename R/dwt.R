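# Discrete wavelet transform (periodized, orthonormal) used for the
# time-frequency GRF feature bank. Implemented from the Daubechies filter
# bank; the periodized construction gives exact perfect reconstruction and
# exact sub-band energy conservation.

wavelet_filters <- function(wavelet) {
  h <- switch(wavelet,
    haar = c(1, 1) / sqrt(2),
    db2 = c(0.48296291314469025, 0.83651630373746899,
            0.22414386804185735, -0.12940952255092145),
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    stop_gaitdx("unknown wavelet: ", wavelet, class = "gaitdx_config_error")
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror high-pass
  list(h = h, g = g)
}

# One periodized analysis step; length(s) must be even.
dwt_step <- function(s, flt) {
  n <- length(s)
  half <- n %/% 2L
  L <- length(flt$h)
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    a <- a + flt$h[m] * s[idx]
    d <- d + flt$g[m] * s[idx]
  }
  list(a = a, d = d)
}

# One periodized synthesis step (transpose of the analysis operator).
idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2L * half
  L <- length(flt$h)
  s <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_len(L)) {
    idx <- (base + (m - 1L)) %% n + 1L
    contrib <- flt$h[m] * a + flt$g[m] * d
    # accumulate; indices within one m are distinct
    s[idx] <- s[idx] + contrib
  }
  s
}

# Symmetric (reflect) padding up to `target` samples.
pad_symmetric <- function(x, target) {
  while (length(x) < target) {
    need <- target - length(x)
    x <- c(x, rev(x)[seq_len(min(need, length(x)))])
  }
  x
}

#' Multilevel discrete wavelet decomposition into named sub-bands
#'
#' Decomposes a segment with an 8-level periodized orthonormal DWT (default
#' wavelet db4) and assembles the 13 named bands used by the time-frequency
#' feature bank: detail coefficients `D1`--`D8`, their concatenation `cD`,
#' approximation signals `A6`--`A8` reconstructed to signal length, and the
#' level-8 approximation coefficients `cA8`. Segments whose length is not a
#' multiple of `2^levels` (or shorter than `2^levels`) are symmetric-reflect
#' padded up to the next multiple before the transform; the padded length is
#' recorded and reconstruction is truncated back to the input length.
#'
#' @param x Numeric segment.
#' @param wavelet Wavelet name: `"db4"` (default), `"db2"` or `"haar"`.
#' @param levels Decomposition depth (default 8).
#' @return Object of class `wavelet_decomposition`: list with `bands` (named
#'   list of 13 coefficient/signal vectors), `wavelet`, `levels`, `length`
#'   (input length) and `padded_length`.
#' @export
dwt_subbands <- function(x, wavelet = "db4", levels = 8L) {
  flt <- wavelet_filters(wavelet)
  n0 <- length(x)
  block <- 2L^levels
  target <- block * max(1L, ceiling(n0 / block))
  xp <- pad_symmetric(x, target)

  details <- vector("list", levels)
  approx <- vector("list", levels)
  s <- xp
  for (l in seq_len(levels)) {
    st <- dwt_step(s, flt)
    details[[l]] <- st$d
    approx[[l]] <- st$a
    s <- st$a
  }
  names(details) <- paste0("D", seq_len(levels))

  # Approximation signal at level l: invert keeping a_l, zeroing all details.
  approx_signal <- function(l) {
    a <- approx[[l]]
    for (j in rev(seq_len(l))) {
      a <- idwt_step(a, numeric(length(a)), flt)
    }
    a[seq_len(target)]
  }

  bands <- c(
    details,
    list(cD = unlist(details, use.names = FALSE)),
    stats::setNames(lapply(6:8, approx_signal), paste0("A", 6:8)),
    list(cA8 = approx[[levels]])
  )
  structure(list(bands = bands, wavelet = wavelet, levels = levels,
                 length = n0, padded_length = target),
            class = "wavelet_decomposition")
}

#' Reconstruct the original segment from a wavelet decomposition
#'
#' Inverts the full 8-level transform from `cA8` and `D1`--`D8`; with the
#' orthonormal periodized construction this is exact (up to floating point),
#' truncated to the original input length.
#'
#' @param dec A `wavelet_decomposition` from [dwt_subbands()].
#' @return Numeric vector of length `dec$length`.
#' @export
reconstruct_signal <- function(dec) {
  stopifnot(inherits(dec, "wavelet_decomposition"))
  flt <- wavelet_filters(dec$wavelet)
  a <- dec$bands$cA8
  for (l in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$bands[[paste0("D", l)]], flt)
  }
  a[seq_len(dec$length)]
}
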