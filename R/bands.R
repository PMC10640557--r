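#' The 16 x 16 phase/amplitude frequency-band grid
#'
#' Phase bands tile 0.5-24 Hz with bandwidths that widen with frequency --
#' 0.5 Hz for 0.5-1 Hz, 1 Hz from 1 to 8 Hz, 2 Hz from 8 to 24 Hz -- giving
#' fine resolution where slow-wave coupling concentrates. Amplitude bands
#' tile the high-frequency-oscillation range 80-560 Hz in 30 Hz steps.
#' Both tilings are contiguous, non-overlapping, and contain exactly 16
#' bands each.
#'
#' @return A list of class `band_grid` with tibbles `phase` and `amplitude`,
#'   each with columns `low` and `high` (Hz).
#' @examples
#' g <- band_grid()
#' nrow(g$phase); nrow(g$amplitude)
#' @export
band_grid <- function() {
  phase_edges <- c(0.5, seq(1, 8, by = 1), seq(10, 24, by = 2))
  amp_edges <- seq(80, 560, by = 30)
  g <- list(
    phase = tibble::tibble(low = phase_edges[-length(phase_edges)],
                           high = phase_edges[-1]),
    amplitude = tibble::tibble(low = amp_edges[-length(amp_edges)],
                               high = amp_edges[-1])
  )
  class(g) <- "band_grid"
  g
}

#' @export
print.band_grid <- function(x, ...) {
  cat("<band_grid> ", nrow(x$phase), " phase bands [",
      min(x$phase$low), "-", max(x$phase$high), " Hz], ",
      nrow(x$amplitude), " amplitude bands [",
      min(x$amplitude$low), "-", max(x$amplitude$high), " Hz]\n", sep = "")
  invisible(x)
}

#' @export
tidy.band_grid <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$phase, role = "phase", index = dplyr::row_number()),
    dplyr::mutate(x$amplitude, role = "amplitude", index = dplyr::row_number())
  )[, c("role", "index", "low", "high")]
}

# Kaiser FIR design targeting >= 60 dB stopband attenuation. The transition
# width is set to half the band's width so that narrow low-frequency bands
# still reach full passband gain at their centre; tap count is clamped to an
# odd value in [101, 20001] (odd length avoids a zero at Nyquist and gives an
# integer group delay).
kaiser_taps <- function(band, fs) {
  atten <- 60
  df <- (band$high - band$low) / 2
  n <- ceiling((atten - 7.95) * fs / (2.285 * 2 * pi * df))
  n <- min(max(n, 101), 20001)
  if (n %% 2 == 0) n <- n + 1
  n
}

kaiser_beta <- function(atten = 60) 0.1102 * (atten - 8.7)

design_fir <- function(band, fs) {
  n_taps <- kaiser_taps(band, fs)
  w <- c(band$low, band$high) / (fs / 2)
  signal::fir1(n_taps - 1, w, type = "pass",
               window = signal::kaiser(n_taps, kaiser_beta()))
}

# Linear convolution via FFT, truncated back to length(x) with the filter's
# integer group delay removed (exact zero phase for a linear-phase FIR of odd
# length).
fft_filter <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - m))),
                     inverse = TRUE)) / nfft
  d <- (m - 1) / 2
  y[(d + 1):(d + n)]
}

#' Zero-phase FIR band-pass filter
#'
#' Kaiser-window FIR design (>= 60 dB stopband, odd tap count) applied with
#' exact group-delay compensation, so the output has no phase lag and the
#' same length as the input. See the methods vignette for the tap-length
#' rule.
#'
#' @param x Numeric series.
#' @param band A list or one-row data frame with `low` and `high` (Hz).
#' @param fs Sampling rate in Hz.
#' @return Filtered series, same length as `x`.
#' @examples
#' fs <- 1000
#' x <- sin(2 * pi * 5 * seq(0, 10, by = 1 / fs))
#' y <- fir_bandpass(x, list(low = 4, high = 6), fs)
#' @export
fir_bandpass <- function(x, band, fs) {
  band <- as.list(band)
  if (!(band$low > 0 && band$low < band$high && band$high < fs / 2)) {
    stop("band must satisfy 0 < low < high < fs/2 (Nyquist = ", fs / 2, " Hz)",
         call. = FALSE)
  }
  h <- design_fir(band, fs)
  if (length(x) <= length(h)) {
    stop("series (", length(x), " samples) must be longer than the filter (",
         length(h), " taps)", call. = FALSE)
  }
  fft_filter(x, h)
}

#' Number of FIR taps used for a band
#'
#' Exposed so users can check filter lengths against their record length;
#' always odd.
#' @inheritParams fir_bandpass
#' @return Odd integer tap count.
#' @export
fir_tap_count <- function(band, fs) {
  band <- as.list(band)
  kaiser_taps(band, fs)
}

# Analytic signal via the frequency-domain Hilbert transformer.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase or amplitude via the Hilbert transform
#'
#' Computes the analytic signal of an already band-limited series and returns
#' either its angle (radians in `(-pi, pi]`) or its magnitude (the
#' instantaneous amplitude envelope, non-negative).
#'
#' @param x_filtered Band-pass-filtered series.
#' @param role `"phase"` or `"amplitude"`.
#' @return Numeric series of the same length. A constant input has no
#'   defined phase; zeros are returned with a warning.
#' @examples
#' fs <- 500
#' x <- cos(2 * pi * 3 * seq(0, 4, by = 1 / fs))
#' amp <- hilbert_phase_amplitude(x, "amplitude")
#' @export
hilbert_phase_amplitude <- function(x_filtered, role = c("phase", "amplitude")) {
  role <- match.arg(role)
  if (stats::sd(x_filtered) == 0) {
    warning("constant input: phase undefined, returning zeros")
    return(numeric(length(x_filtered)))
  }
  z <- analytic_signal(x_filtered)
  if (role == "phase") Arg(z) else Mod(z)
}

#' Split a series into fixed-length chronological segments
#'
#' Non-overlapping windows of `seg_seconds` seconds in recording order; a
#' trailing remainder shorter than one window is discarded. One continuous
#' hour at the default 20-s window yields 180 segments.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param seg_seconds Window length in seconds (default 20). `fs *
#'   seg_seconds` must be an integer.
#' @return Matrix of class `segmented_series` with one row per segment
#'   (chronological) and `fs * seg_seconds` columns; attributes `fs` and
#'   `seg_seconds`. Zero rows (with a warning) if `x` is shorter than one
#'   window.
#' @examples
#' seg <- segment_series(rnorm(5000), fs = 100, seg_seconds = 10)
#' nrow(seg)
#' @export
segment_series <- function(x, fs, seg_seconds = 20) {
  len <- fs * seg_seconds
  if (abs(len - round(len)) > 1e-8) {
    stop("fs * seg_seconds must be an integer sample count", call. = FALSE)
  }
  len <- round(len)
  k <- length(x) %/% len
  if (k == 0) {
    warning("series shorter than one segment; returning no segments")
    m <- matrix(numeric(0), nrow = 0, ncol = len)
  } else {
    m <- matrix(x[seq_len(k * len)], nrow = k, ncol = len, byrow = TRUE)
  }
  structure(m, fs = fs, seg_seconds = seg_seconds, class = "segmented_series")
}
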