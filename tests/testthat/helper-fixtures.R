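# Small shared builders so individual tests stay fast.

tiny_cfg <- function(epochs = 2L, seed = 7L) {
  model_config(input_length = 64L, conv_filters = c(4L, 6L, 8L),
               kernel_size = 3L, dense_units = c(16L, 12L),
               dropout_p = 0.2, n_classes = 5L, batch_size = 16L,
               epochs = epochs, seed = seed)
}

tiny_dataset <- function(n_per_class = 6L, length = 64L, seed = 3L) {
  ds <- generate_dataset(n_per_class, length = length, seed = seed)
  assign_splits(ds, c(train = 0.7, val = 0.15, test = 0.15), seed = seed)
}

# FFT amplitude of the bin nearest freq_hz over a central window.
fft_amplitude <- function(samples, fs, freq_hz, window = seq_along(samples)) {
  x <- samples[window]
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  bin <- round(freq_hz * n / fs) + 1L
  sp[bin]
}

rms <- function(x) sqrt(mean(x^2))
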