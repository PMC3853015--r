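# Zero-phase frequency-domain filtering.
#
# No IIR filter-design package is assumed: filtering multiplies the spectrum
# by the magnitude-SQUARED response of a Butterworth filter, which is exactly
# the amplitude response of applying that Butterworth forward and backward
# (filtfilt) while having identically zero phase. Signals are mirror-padded
# before the FFT to suppress circular edge effects.

# Butterworth band-pass |H(f)|^2 of the given order; zero at DC.
butter_bp_gain <- function(f, low, high, order = 5) {
  g <- numeric(length(f))
  fa <- abs(f)
  nz <- fa > 0
  u <- (fa[nz]^2 - low * high) / (fa[nz] * (high - low))
  g[nz] <- 1 / (1 + u^(2 * order))
  g
}

# Butterworth low-pass |H(f)|^2.
butter_lp_gain <- function(f, cutoff, order = 8) {
  1 / (1 + (abs(f) / cutoff)^(2 * order))
}

# Apply a frequency-domain gain to every row signal of a channels x samples
# matrix, with mirror padding of `pad` samples on each side.
fft_filter_mat <- function(x, fs, gain_fun, pad = NULL) {
  n <- ncol(x)
  if (is.null(pad)) pad <- min(n - 1L, as.integer(round(fs)))
  idx <- c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
  xp <- x[, idx, drop = FALSE]
  np <- ncol(xp)
  f <- c(seq(0, floor(np / 2)), seq(-ceiling(np / 2) + 1, -1)) * (fs / np)
  g <- gain_fun(f)
  xf <- t(stats::mvfft(t(xp)))
  xf <- sweep(xf, 2L, g, `*`)
  out <- Re(t(stats::mvfft(t(xf), inverse = TRUE))) / np
  out[, pad + seq_len(n), drop = FALSE]
}

apply_per_trial <- function(e, fun) {
  out <- e$data
  for (i in seq_len(n_trials(e))) {
    m <- fun(trial_matrix(e, i))
    out[i, , ] <- m
  }
  out
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean over channels, so each
#' channel is re-referenced to the scalp average. Idempotent and invariant to
#' common-mode offsets.
#'
#' @param e an [epochs] object with at least 2 channels
#' @return an [epochs] object of the same shape; the channel mean at every
#'   sample is 0.
#' @export
common_average_reference <- function(e) {
  validate_epochs(e)
  if (n_channels(e) < 2L) stop("common average reference needs >= 2 channels")
  e$data <- apply_per_trial(e, function(m) sweep(m, 2L, colMeans(m)))
  e
}

#' Zero-phase band-pass filter
#'
#' Band-pass with the amplitude response of a forward-backward (zero-phase)
#' 5th-order Butterworth: passband sinusoids are preserved within 5% in
#' amplitude, DC is removed, and no phase distortion is introduced (the
#' response is applied as a real frequency-domain gain).
#'
#' @param e an [epochs] object
#' @param low,high band edges in Hz, `0 < low < high < fs/2`
#' @param order filter order (the applied gain is the order-`order`
#'   Butterworth magnitude squared)
#' @return filtered [epochs]
#' @export
bandpass <- function(e, low, high, order = 5) {
  validate_epochs(e)
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= e$fs / 2) stop("high band edge must be below Nyquist (fs/2 = ",
                             e$fs / 2, " Hz)")
  pad <- min(n_samples(e) - 1L, as.integer(ceiling(3 * e$fs / low)))
  e$data <- apply_per_trial(e, function(m)
    fft_filter_mat(m, e$fs, function(f) butter_bp_gain(f, low, high, order), pad))
  e
}

#' Downsample with anti-alias filtering
#'
#' Applies an order-8 Butterworth-magnitude low-pass at 0.8x the new Nyquist
#' frequency, then decimates by the integer factor `fs / target_fs`.
#'
#' @param e an [epochs] object
#' @param target_fs new sampling rate in Hz; `fs` must be an integer multiple
#' @return an [epochs] object at `target_fs` with
#'   `floor(samples * target_fs / fs)` samples.
#' @export
downsample <- function(e, target_fs) {
  validate_epochs(e)
  ratio <- e$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fs (", e$fs, ") must be an integer multiple of target_fs (", target_fs, ")")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(e)
  cutoff <- 0.4 * target_fs
  ns_new <- floor(n_samples(e) * target_fs / e$fs)
  idx <- seq(1L, by = ratio, length.out = ns_new)
  d <- dim(e$data)
  out <- array(0, c(d[1L], d[2L], ns_new))
  for (i in seq_len(d[1L])) {
    m <- fft_filter_mat(trial_matrix(e, i), e$fs,
                        function(f) butter_lp_gain(f, cutoff, 8))
    out[i, , ] <- m[, idx, drop = FALSE]
  }
  e$data <- out
  e$fs <- target_fs
  e
}

#' Crop epochs to a time interval
#'
#' @param e an [epochs] object
#' @param t_start,t_end interval bounds in seconds relative to trial start
#'   (the package convention is t = 0 at trial start, imagery cue at 3 s, so
#'   the imagery window "0.5 s to 3.5 s after cue" is `c(3.5, 6.5)`).
#' @return an [epochs] object with `round((t_end - t_start) * fs)` samples and
#'   `t0 = t_start`.
#' @export
crop_interval <- function(e, t_start, t_end) {
  validate_epochs(e)
  dur <- n_samples(e) / e$fs
  if (!(t_start >= e$t0 - 1e-9 && t_start < t_end && t_end <= e$t0 + dur + 1e-9))
    stop(sprintf("interval [%g, %g] outside trial extent [%g, %g]",
                 t_start, t_end, e$t0, e$t0 + dur))
  ns <- as.integer(round((t_end - t_start) * e$fs))
  start <- as.integer(round((t_start - e$t0) * e$fs)) + 1L
  ns <- min(ns, n_samples(e) - start + 1L)
  e$data <- e$data[, , start:(start + ns - 1L), drop = FALSE]
  e$t0 <- t_start
  e
}

#' The standard preprocessing chain
#'
#' Applies, in order: common average reference, band-pass, downsampling and
#' interval cropping, each optional. The order is fixed; each applied stage is
#' logged via `message()` when `verbose = TRUE`.
#'
#' @param e an [epochs] object
#' @param car apply common average reference?
#' @param band numeric length-2 band in Hz, or `NULL` to skip
#' @param target_fs target rate in Hz, or `NULL` to skip
#' @param interval numeric length-2 crop interval in seconds, or `NULL`
#' @param verbose log each stage?
#' @return preprocessed [epochs]
#' @export
preprocess <- function(e, car = TRUE, band = c(8, 30), target_fs = NULL,
                       interval = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("preprocess: ", ...)
  if (isTRUE(car)) { e <- common_average_reference(e); say("CAR") }
  if (!is.null(band)) {
    e <- bandpass(e, band[1L], band[2L])
    say(sprintf("band-pass %g-%g Hz", band[1L], band[2L]))
  }
  if (!is.null(target_fs) && target_fs != e$fs) {
    e <- downsample(e, target_fs)
    say(sprintf("downsample to %g Hz", target_fs))
  }
  if (!is.null(interval)) {
    e <- crop_interval(e, interval[1L], interval[2L])
    say(sprintf("crop [%g, %g] s", interval[1L], interval[2L]))
  }
  e
}
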