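# Small in-code fixtures shared across tests.

# random epochs with balanced labels over `classes`
random_epochs <- function(n_per = 2, n_ch = 4, n_s = 64, fs = 64,
                          classes = 1:7, seed = 1,
                          channels = paste0("ch", seq_len(n_ch))) {
  withr::with_seed(seed, {
    n <- n_per * length(classes)
    epochs(array(rnorm(n * n_ch * n_s), c(n, n_ch, n_s)),
           labels = rep(classes, each = n_per), fs = fs, channels = channels)
  })
}

# epochs holding one pure sinusoid on every channel
tone_epochs <- function(freq, fs = 200, dur = 8, n_ch = 2, amp = 1) {
  t <- seq_len(dur * fs) / fs
  x <- amp * sin(2 * pi * freq * t)
  epochs(array(rep(x, each = n_ch), c(1, n_ch, length(x))), 1L, fs,
         paste0("ch", seq_len(n_ch)))
}

# random symmetric positive-definite matrix
random_spd <- function(n, seed = NULL) {
  gen <- function() {
    a <- matrix(rnorm(n * n), n)
    crossprod(a) + diag(n) * 0.1
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# FFT amplitude of a sinusoid component at frequency f0
fft_amplitude <- function(x, fs, f0) {
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  a <- Mod(stats::fft(x)) * 2 / n
  a[which.min(abs(f - f0))]
}

# small central montage containing the source electrodes, for cheap runs
central_montage <- function() {
  c("FC3", "FC1", "FCZ", "FC2", "FC4", "C5", "C3", "C1", "CZ", "C2", "C4",
    "C6", "CP3", "CP1", "CPZ", "CP2", "CP4")
}

expect_symmetric_psd <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), 1e-8)
  expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), -tol)
}
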