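#' Surrogate specification for modulation-index z-scoring
#'
#' Controls the circular time-shift surrogate ensemble used to normalize the
#' raw mean-vector-length modulation index. Each surrogate rotates the phase
#' series by a random shift drawn uniformly from `[min_shift, N - min_shift]`
#' samples, which preserves the phase marginal while destroying any
#' phase-amplitude alignment.
#'
#' @param n_surrogates Number of surrogates (default 100, minimum 2).
#' @param min_shift Minimum shift in samples. `NULL` (default) resolves to
#'   one second of samples when a sampling rate is known, else to 5% of the
#'   segment length; this keeps surrogates away from near-identity shifts.
#' @param seed Integer base seed. The pipeline derives a per
#'   (channel, segment, cell) key from it so results are reproducible and
#'   independent of execution order.
#' @return A list of class `surrogate_spec`.
#' @export
surrogate_spec <- function(n_surrogates = 100, min_shift = NULL, seed = 1L) {
  if (n_surrogates < 2) stop("n_surrogates must be >= 2", call. = FALSE)
  structure(list(n_surrogates = as.integer(n_surrogates),
                 min_shift = min_shift, seed = as.integer(seed)),
            class = "surrogate_spec")
}

resolve_min_shift <- function(spec, n, fs = NULL) {
  ms <- spec$min_shift
  if (is.null(ms)) ms <- if (!is.null(fs)) round(fs) else max(1, round(0.05 * n))
  ms <- as.integer(ms)
  if (ms <= 0 || ms >= n) {
    stop("min_shift must satisfy 0 < min_shift < segment length (", n, ")",
         call. = FALSE)
  }
  ms
}

#' Raw mean-vector-length modulation index
#'
#' The modulus of the time-mean of the complex composite
#' `z(t) = A(t) * exp(i * phi(t))`: amplitude samples are treated as vectors
#' pointing at the concurrent phase, and any systematic clustering of high
#' amplitude at a preferred phase leaves a non-zero mean vector.
#'
#' @param phase Phase series in radians.
#' @param amplitude Non-negative amplitude series, same length.
#' @return Non-negative scalar.
#' @examples
#' phi <- seq(0, 20 * pi, length.out = 4001)[-1]
#' mvl_raw(phi, 1 + cos(phi))   # ~0.5
#' @export
mvl_raw <- function(phase, amplitude) {
  if (length(phase) != length(amplitude)) {
    stop("phase and amplitude must have equal length", call. = FALSE)
  }
  if (length(phase) < 2) stop("need at least 2 samples", call. = FALSE)
  Mod(mean(amplitude * exp(1i * phase)))
}

# MI_raw for any circular shift of the phase series:
# C(s) = sum_t A(t) u(t + s) with u = exp(i*phi) is a cross-correlation, so
# C = IFFT(FFT(u) * Conj(FFT(A))) and MI_raw(s) = |C(s)| / N. Shift 0
# recovers the observed index; the surrogate ensemble samples the rest, so
# the modulus is only evaluated at the drawn shifts.
surrogate_z_core <- function(fft_u, fft_a_conj, n, spec, key, min_shift) {
  cc <- stats::fft(fft_u * fft_a_conj, inverse = TRUE)
  set.seed(as.integer((as.double(spec$seed) + as.double(key)) %% 2147483647))
  shifts <- sample(min_shift:(n - min_shift), spec$n_surrogates,
                   replace = TRUE)
  mi_raw <- Mod(cc[1]) / (n * n)
  mi_surr <- Mod(cc[shifts + 1]) / (n * n)
  mu <- mean(mi_surr)
  sigma <- stats::sd(mi_surr)
  # shift-invariant inputs (e.g. constant amplitude) leave only rounding
  # noise in the surrogate spread; treat that as degenerate
  if (!is.finite(sigma) || sigma <= 1e-10 * max(mu, mi_raw)) {
    warning("surrogate spread is degenerate (shift-invariant input); ",
            "returning 0")
    return(0)
  }
  (mi_raw - mu) / sigma
}

#' Surrogate-normalized modulation index (z-scored MVL-MI)
#'
#' Computes `MI = (MI_raw - mu) / sigma`, where `mu` and `sigma` are the mean
#' and sample standard deviation of the raw index recomputed over
#' `n_surrogates` circular time shifts of the phase series. Under the null of
#' no coupling the result is approximately standard normal; values above ~3
#' indicate coupling unlikely to arise by chance. The z-score is invariant
#' under global rescaling of the amplitude.
#'
#' @inheritParams mvl_raw
#' @param spec A [surrogate_spec()].
#' @param key Integer offset added to `spec$seed` for this call; the pipeline
#'   keys it by (channel, segment, cell).
#' @param fs Optional sampling rate, used only to resolve a default
#'   `min_shift` of one second.
#' @return Scalar z-scored modulation index (may be negative; not clipped).
#'   Shift-invariant inputs -- a constant amplitude, or any input whose
#'   surrogate spread is pure rounding noise -- return 0 with a warning.
#' @export
surrogate_z <- function(phase, amplitude, spec = surrogate_spec(), key = 0,
                        fs = NULL) {
  if (length(phase) != length(amplitude)) {
    stop("phase and amplitude must have equal length", call. = FALSE)
  }
  n <- length(phase)
  ms <- resolve_min_shift(spec, n, fs)
  surrogate_z_core(stats::fft(exp(1i * phase)),
                   Conj(stats::fft(amplitude)), n, spec, key, ms)
}

band_label <- function(bands) sprintf("%g-%g", bands$low, bands$high)

#' Comodulogram for one channel-segment
#'
#' Evaluates the z-scored modulation index for every (phase band, amplitude
#' band) pair and arranges the results with amplitude bands in rows and
#' phase bands in columns -- the orientation of the usual comodulogram plot
#' (x = frequency for phase, y = frequency for amplitude).
#'
#' @param phase Matrix (samples x 16) of instantaneous phase, one column per
#'   phase band in grid order.
#' @param amplitude Matrix (samples x 16) of instantaneous amplitude, one
#'   column per amplitude band in grid order.
#' @param grid A [band_grid()] (used for dimension names and validation).
#' @param spec A [surrogate_spec()].
#' @param key_base Integer base for the per-cell surrogate keys; cell
#'   `(a, p)` uses `key_base + (a - 1) * 16 + (p - 1)`.
#' @param fs Optional sampling rate for the default `min_shift`.
#' @return 16 x 16 numeric matrix of z-scored modulation indices.
#' @export
comodulogram <- function(phase, amplitude, grid = band_grid(),
                         spec = surrogate_spec(), key_base = 0, fs = NULL) {
  n_p <- nrow(grid$phase)
  n_a <- nrow(grid$amplitude)
  if (!is.matrix(phase) || ncol(phase) != n_p) {
    stop("phase must have one column per phase band; missing bands: ",
         paste(band_label(grid$phase)[-seq_len(ncol(as.matrix(phase)))],
               collapse = ", "), call. = FALSE)
  }
  if (!is.matrix(amplitude) || ncol(amplitude) != n_a) {
    stop("amplitude must have one column per amplitude band; missing bands: ",
         paste(band_label(grid$amplitude)[-seq_len(ncol(as.matrix(amplitude)))],
               collapse = ", "), call. = FALSE)
  }
  n <- nrow(phase)
  ms <- resolve_min_shift(spec, n, fs)
  fft_u <- apply(exp(1i * phase), 2, stats::fft)
  fft_ac <- Conj(apply(amplitude, 2, stats::fft))
  out <- matrix(NA_real_, n_a, n_p,
                dimnames = list(band_label(grid$amplitude),
                                band_label(grid$phase)))
  for (a in seq_len(n_a)) {
    for (p in seq_len(n_p)) {
      key <- key_base + (a - 1) * n_p + (p - 1)
      out[a, p] <- surrogate_z_core(fft_u[, p], fft_ac[, a], n, spec, key, ms)
    }
  }
  out
}

# Precomputed frequency-domain filter bank: per band, the zero-padded FFT
# of the Kaiser FIR multiplied by the analytic-signal mask, so band-pass
# filtering and the Hilbert transform together cost one inverse FFT. The
# bank is built once per recording and shared across channels.
build_filter_bank <- function(bands, fs, n) {
  hs <- lapply(seq_len(nrow(bands)), function(b) design_fir(bands[b, ], fs))
  m_max <- max(lengths(hs))
  if (n <= m_max) {
    stop("recording (", n, " samples) must be longer than the longest ",
         "filter (", m_max, " taps)", call. = FALSE)
  }
  nfft <- stats::nextn(n + m_max - 1, c(2, 3, 5))
  mask <- numeric(nfft)
  if (nfft %% 2 == 0) {
    mask[c(1, nfft / 2 + 1)] <- 1
    mask[2:(nfft / 2)] <- 2
  } else {
    mask[1] <- 1
    mask[2:((nfft + 1) / 2)] <- 2
  }
  list(nfft = nfft, n = n,
       H = lapply(hs, function(h) {
         stats::fft(c(h, numeric(nfft - length(h)))) * mask
       }),
       delay = vapply(hs, function(h) (length(h) - 1) / 2, numeric(1)))
}

# Analytic (complex) band series for band b, given the channel's padded FFT;
# the filter's integer group delay is removed, leaving a zero-phase result.
bank_analytic <- function(X, bank, b) {
  y <- stats::fft(X * bank$H[[b]], inverse = TRUE) / bank$nfft
  d <- bank$delay[b]
  y[(d + 1):(d + bank$n)]
}

# Filter one channel into every band of one role and return the segmented
# phase/amplitude series as a (segments x samples x bands) array.
segmented_analytic <- function(x, bands, role, fs, seg_seconds,
                               bank = NULL, X = NULL) {
  seg_len <- round(fs * seg_seconds)
  n_seg <- length(x) %/% seg_len
  if (is.null(bank)) bank <- build_filter_bank(bands, fs, length(x))
  if (is.null(X)) X <- stats::fft(c(x, numeric(bank$nfft - length(x))))
  out <- array(NA_real_, c(n_seg, seg_len, nrow(bands)))
  keep <- seq_len(n_seg * seg_len)
  for (b in seq_len(nrow(bands))) {
    z <- bank_analytic(X, bank, b)
    series <- if (role == "phase") Arg(z) else Mod(z)
    out[, , b] <- matrix(series[keep], nrow = n_seg, byrow = TRUE)
  }
  out
}

#' Compute the comodulogram tensor for a labeled recording
#'
#' The full feature-extraction pipeline: each channel is band-pass filtered
#' into the 16 phase and 16 amplitude bands, instantaneous phase/amplitude
#' are extracted with the Hilbert transform, the series are cut into
#' non-overlapping 20-s segments, and a surrogate-normalized 16 x 16
#' comodulogram is computed per channel-segment. Surrogate draws are keyed by
#' (channel, segment, cell), so results do not depend on evaluation order.
#'
#' @param rec A [labeled_recording()].
#' @param grid A [band_grid()].
#' @param spec A [surrogate_spec()]; a `NULL` `min_shift` resolves to one
#'   second of samples.
#' @param seg_seconds Segment length in seconds (default 20).
#' @param verbose Print per-channel progress.
#' @return A `comodulogram_tensor`: list with `values` (array channel x
#'   segment x 16 amplitude x 16 phase), `grid`, `channels` (tibble with
#'   `channel`, `label`), `fs`, `seg_seconds`, `spec`.
#' @examples
#' \donttest{
#' rec <- generate_recording(synth_config(fs = 1200, duration = 40,
#'                                        n_soz = 1, n_nsoz = 1))
#' ten <- compute_comodulograms(rec, spec = surrogate_spec(20))
#' dim(ten$values)
#' }
#' @export
compute_comodulograms <- function(rec, grid = band_grid(),
                                  spec = surrogate_spec(), seg_seconds = 20,
                                  verbose = FALSE) {
  stopifnot(inherits(rec, "labeled_recording"))
  n_ch <- nrow(rec$data)
  seg_len <- round(rec$fs * seg_seconds)
  n_seg <- ncol(rec$data) %/% seg_len
  if (n_seg == 0) stop("recording shorter than one segment", call. = FALSE)
  n_p <- nrow(grid$phase)
  n_a <- nrow(grid$amplitude)
  values <- array(NA_real_, c(n_ch, n_seg, n_a, n_p))
  n_samp <- ncol(rec$data)
  bank_p <- build_filter_bank(grid$phase, rec$fs, n_samp)
  bank_a <- build_filter_bank(grid$amplitude, rec$fs, n_samp)
  for (ch in seq_len(n_ch)) {
    if (verbose) message("channel ", ch, "/", n_ch)
    x <- rec$data[ch, ]
    ph <- segmented_analytic(x, grid$phase, "phase", rec$fs, seg_seconds,
                             bank = bank_p,
                             X = stats::fft(c(x, numeric(bank_p$nfft -
                                                           n_samp))))
    am <- segmented_analytic(x, grid$amplitude, "amplitude", rec$fs,
                             seg_seconds, bank = bank_a,
                             X = stats::fft(c(x, numeric(bank_a$nfft -
                                                           n_samp))))
    for (s in seq_len(n_seg)) {
      key_base <- ((ch - 1) * 100000 + (s - 1)) * (n_a * n_p)
      values[ch, s, , ] <- comodulogram(ph[s, , ], am[s, , ], grid, spec,
                                        key_base = key_base, fs = rec$fs)
    }
  }
  structure(
    list(values = values, grid = grid, channels = rec$channels,
         fs = rec$fs, seg_seconds = seg_seconds, spec = spec),
    class = "comodulogram_tensor"
  )
}

#' @export
print.comodulogram_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("<comodulogram_tensor> ", d[1], " channels x ", d[2], " segments x ",
      d[3], "x", d[4], " (amplitude x phase) z-scored MI\n", sep = "")
  invisible(x)
}

#' Tidy a comodulogram tensor into a long tibble
#'
#' @param x A `comodulogram_tensor`.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `label`, `segment`,
#'   `phase_low`, `phase_high`, `amp_low`, `amp_high`, `mi`.
#' @export
tidy.comodulogram_tensor <- function(x, ...) {
  d <- dim(x$values)
  grid <- tidyr::expand_grid(
    ch = seq_len(d[1]), seg = seq_len(d[2]), a = seq_len(d[3]),
    p = seq_len(d[4])
  )
  tibble::tibble(
    channel = x$channels$channel[grid$ch],
    label = x$channels$label[grid$ch],
    segment = grid$seg,
    phase_low = x$grid$phase$low[grid$p],
    phase_high = x$grid$phase$high[grid$p],
    amp_low = x$grid$amplitude$low[grid$a],
    amp_high = x$grid$amplitude$high[grid$a],
    mi = x$values[as.matrix(grid[, c("ch", "seg", "a", "p")])]
  )
}

#' Persist a comodulogram tensor as a delimited-text table
#'
#' Writes the tensor in long form (one row per channel, segment and grid
#' cell) so results can be archived or exchanged without binary formats;
#' `read_comodulograms()` reconstructs the tensor.
#'
#' @param tensor A `comodulogram_tensor`.
#' @param path Output TSV path.
#' @return `tensor`, invisibly.
#' @export
write_comodulograms <- function(tensor, path) {
  df <- tidy.comodulogram_tensor(tensor)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tensor)
}

#' @rdname write_comodulograms
#' @param fs,seg_seconds Recording metadata to restore (not serialized).
#' @export
read_comodulograms <- function(path, fs = NA_real_, seg_seconds = 20) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  grid <- band_grid()
  channels <- unique(df[, c("channel", "label")])
  ch_i <- match(df$channel, channels$channel)
  a_i <- match(df$amp_low, grid$amplitude$low)
  p_i <- match(df$phase_low, grid$phase$low)
  if (anyNA(a_i) || anyNA(p_i)) {
    stop("table bands do not match the 16 x 16 analysis grid", call. = FALSE)
  }
  values <- array(NA_real_, c(nrow(channels), max(df$segment),
                              nrow(grid$amplitude), nrow(grid$phase)))
  values[cbind(ch_i, df$segment, a_i, p_i)] <- df$mi
  structure(
    list(values = values, grid = grid,
         channels = tibble::as_tibble(channels), fs = fs,
         seg_seconds = seg_seconds, spec = NULL),
    class = "comodulogram_tensor"
  )
}

#' Plot mean comodulograms by channel label
#'
#' Heat map of the time-averaged comodulogram, averaged within SOZ and NSOZ
#' channel groups, with phase frequency on x and amplitude frequency on y.
#'
#' @param object A `comodulogram_tensor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comodulogram_tensor <- function(object, ...) {
  df <- tidy.comodulogram_tensor(object)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$label, .data$phase_low, .data$phase_high,
                    .data$amp_low, .data$amp_high),
    mi = mean(.data$mi), .groups = "drop"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    xmin = .data$phase_low, xmax = .data$phase_high,
    ymin = .data$amp_low, ymax = .data$amp_high, fill = .data$mi
  )) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~label) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "Frequency for phase (Hz)",
                  y = "Frequency for amplitude (Hz)",
                  fill = "z-scored MI")
}
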