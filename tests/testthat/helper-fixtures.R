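# Shared fixtures, all generated in code at test time.

# Independent phase/amplitude pair (no coupling) from two independent
# narrowband noise processes; cheap null segments for calibration tests.
null_segment <- function(fs = 250, seconds = 20, seed = 1) {
  set.seed(seed)
  n <- fs * seconds
  ph <- hilbert_phase_amplitude(
    fir_bandpass(stats::rnorm(n + 2 * fs), list(low = 3, high = 4), fs),
    "phase"
  )[fs:(fs + n - 1)]
  am <- hilbert_phase_amplitude(
    fir_bandpass(stats::rnorm(n + 2 * fs), list(low = 30, high = 40), fs),
    "amplitude"
  )[fs:(fs + n - 1)]
  list(phase = ph, amplitude = am)
}

# A comodulogram tensor whose values are pure noise except for a strong,
# clean offset in SOZ channels; used to exercise classifiers and the nested
# CV without paying for signal processing.
make_fake_features <- function(n_soz = 2, n_nsoz = 6, n_seg = 24, shift = 3,
                               seed = 1) {
  set.seed(seed)
  n_ch <- n_soz + n_nsoz
  labels <- c(rep("SOZ", n_soz), rep("NSOZ", n_nsoz))
  values <- array(stats::rnorm(n_ch * n_seg * 256), c(n_ch, n_seg, 16, 16))
  values[seq_len(n_soz), , 2:4, 3:5] <-
    values[seq_len(n_soz), , 2:4, 3:5] + shift
  ten <- structure(
    list(values = values, grid = band_grid(),
         channels = tibble::tibble(channel = sprintf("ch%02d", seq_len(n_ch)),
                                   label = labels),
         fs = 1200, seg_seconds = 20, spec = surrogate_spec()),
    class = "comodulogram_tensor"
  )
  as_feature_matrix(ten)
}

# Permute segment-level labels of a pac_features object (breaks any
# label-feature association; the null for classifier tests).
permute_labels <- function(features, seed = 1) {
  set.seed(seed)
  perm <- sample(nrow(features$X))
  features$meta$y <- features$meta$y[perm]
  features$meta$label <- features$meta$label[perm]
  features
}

# Reference z-scored MI computed by explicit circular shifting, independent
# of the FFT cross-correlation fast path.
brute_force_z <- function(phase, amplitude, spec, min_shift) {
  n <- length(phase)
  mi_raw <- Mod(mean(amplitude * exp(1i * phase)))
  set.seed(as.integer(spec$seed %% 2147483647))
  shifts <- sample(min_shift:(n - min_shift), spec$n_surrogates,
                   replace = TRUE)
  mis <- vapply(shifts, function(s) {
    idx <- ((seq_len(n) - 1 + s) %% n) + 1
    Mod(mean(amplitude * exp(1i * phase[idx])))
  }, numeric(1))
  (mi_raw - mean(mis)) / stats::sd(mis)
}
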