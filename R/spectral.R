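# Time-frequency and spectral-entropy features.
#
# The spectral estimator is a short-time Fourier transform with a Hann window
# (default 0.5 s, 90% overlap), evaluated by direct DFT on an arbitrary
# frequency grid (default 1-35 Hz in 0.5 Hz steps) and scaled as a one-sided
# power spectral density. Event-related spectral perturbation (ERSP) is the
# trial-mean power divided by the per-frequency mean baseline power, in dB:
# negative values are event-related desynchronization (ERD), positive values
# synchronization (ERS).

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Short-time spectral power of one signal
#'
#' @param x numeric vector, one trial of one channel (microvolts)
#' @param fs sampling rate in Hz
#' @param window_sec Hann window length in seconds
#' @param overlap fractional window overlap in `[0, 1)`
#' @param freqs frequency grid in Hz
#' @return a `tf_power` object: list with `freqs`, `times` (window centers in
#'   seconds from the start of `x`) and `power` (freq x time, one-sided PSD,
#'   microvolt^2/Hz).
#' @export
tf_power <- function(x, fs, window_sec = 0.5, overlap = 0.9,
                     freqs = seq(1, 35, by = 0.5)) {
  n <- length(x)
  wlen <- max(2L, as.integer(round(window_sec * fs)))
  if (wlen > n) stop("window (", wlen, " samples) longer than signal (", n, ")")
  hop <- max(1L, as.integer(round(wlen * (1 - overlap))))
  starts <- seq(1L, n - wlen + 1L, by = hop)
  w <- hann_window(wlen)
  # direct DFT on the requested grid: exact at arbitrary frequencies
  basis <- exp(-2i * pi * outer(freqs, 0:(wlen - 1L)) / fs)
  frames <- vapply(starts, function(s) x[s:(s + wlen - 1L)] * w,
                   numeric(wlen))
  p <- Mod(basis %*% frames)^2 * (2 / (fs * sum(w^2)))
  structure(list(freqs = freqs, times = (starts - 1 + (wlen - 1) / 2) / fs,
                 power = p),
            class = "tf_power")
}

class_trials <- function(e, class_id) {
  idx <- which(e$labels == class_id)
  if (!length(idx)) stop("no trials with label ", class_id)
  idx
}

channel_index <- function(e, channel) {
  j <- match(toupper(channel), toupper(e$channels))
  if (is.na(j)) stop("unknown channel: ", channel)
  j
}

#' Event-related spectral perturbation map
#'
#' Mean spectral power over all trials of one class at one channel, expressed
#' in dB relative to the per-frequency mean power in the baseline window.
#'
#' @param e an [epochs] object
#' @param class_id task label (1-7)
#' @param channel channel name
#' @param baseline length-2 baseline window in seconds (trial time); default
#'   the 3 s pre-cue period
#' @param window_sec,overlap,freqs forwarded to [tf_power()]
#' @return an `ersp_map` object: list with `freqs`, `times` (trial time, s),
#'   `values` (freq x time, dB), `n_trials`, and the intermediate trial-mean
#'   power `mean_power` and per-frequency `baseline_power`.
#' @export
ersp <- function(e, class_id, channel, baseline = c(0, 3), window_sec = 0.5,
                 overlap = 0.9, freqs = seq(1, 35, by = 0.5)) {
  idx <- class_trials(e, class_id)
  j <- channel_index(e, channel)
  acc <- NULL
  for (i in idx) {
    tf <- tf_power(e$data[i, j, ], e$fs, window_sec, overlap, freqs)
    acc <- if (is.null(acc)) tf$power else acc + tf$power
  }
  meanp <- acc / length(idx)
  times <- tf$times + e$t0
  bidx <- which(times >= baseline[1L] - 1e-9 & times <= baseline[2L] + 1e-9)
  if (!length(bidx))
    stop(sprintf("baseline [%g, %g] s contains no STFT frames", baseline[1L],
                 baseline[2L]))
  bp <- rowMeans(meanp[, bidx, drop = FALSE])
  if (any(bp <= 0)) stop("baseline power is zero at some frequency")
  structure(list(freqs = freqs, times = times,
                 values = 10 * log10(meanp / bp),
                 n_trials = length(idx), mean_power = meanp,
                 baseline_power = bp),
            class = "ersp_map")
}

#' Mean power-change curve over the imagery period
#'
#' Averages ERSP values over the imagination window per frequency for each
#' subject, then over subjects, giving the power change (dB) as a function of
#' frequency.
#'
#' @param maps list of `ersp_map` objects, one per subject, on a common grid
#' @param imagery length-2 imagery window in seconds (trial time)
#' @return list with `freqs`, `values` (grand-mean dB per frequency) and
#'   `per_subject` (subjects x freq matrix).
#' @export
band_power_curve <- function(maps, imagery = c(3, 7)) {
  if (inherits(maps, "ersp_map")) maps <- list(maps)
  f0 <- maps[[1L]]$freqs
  per <- t(vapply(maps, function(m) {
    if (length(m$freqs) != length(f0) || any(abs(m$freqs - f0) > 1e-9))
      stop("ERSP maps are not on a common frequency grid")
    tidx <- which(m$times >= imagery[1L] - 1e-9 & m$times <= imagery[2L] + 1e-9)
    if (!length(tidx)) stop("imagery window contains no STFT frames")
    rowMeans(m$values[, tidx, drop = FALSE])
  }, numeric(length(f0))))
  list(freqs = f0, values = colMeans(per), per_subject = per)
}

#' Per-frequency paired t-test between two conditions
#'
#' Tests, frequency bin by frequency bin, whether the per-subject power
#' curves of two conditions differ (two-sided paired t, uncorrected).
#'
#' @param a,b subjects x frequency matrices (e.g. the `per_subject` element of
#'   [band_power_curve()]), same subjects in the same row order
#' @param alpha significance level for the mask
#' @return data.frame with columns `freq` (if `freqs` given), `t`, `p`, `sig`.
#' @param freqs optional frequency grid for labelling
#' @export
paired_freq_ttest <- function(a, b, alpha = 0.05, freqs = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("conditions have mismatched subjects or grids")
  if (nrow(a) < 2L) stop("paired t-test needs >= 2 subjects")
  d <- a - b
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  # zero-variance differences: t = 0 (p = 1) when the means agree, NA (not
  # assessable, hence not significant) when they do not
  t <- ifelse(s == 0, ifelse(m == 0, 0, NA_real_), m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  p[t == 0 & s == 0] <- 1
  out <- data.frame(t = t, p = p, sig = !is.na(p) & p < alpha)
  if (!is.null(freqs)) out <- cbind(freq = freqs, out)
  rownames(out) <- NULL
  out
}

#' Welch power spectral density
#'
#' Mean of Hann-windowed one-sided periodograms over 50%-overlapping segments.
#'
#' @param x numeric signal
#' @param fs sampling rate (Hz)
#' @param seg_sec segment length in seconds
#' @param overlap fractional overlap
#' @return list with `freqs` and `psd` (microvolt^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_sec = 1, overlap = 0.5) {
  n <- length(x)
  wlen <- min(n, max(2L, as.integer(round(seg_sec * fs))))
  hop <- max(1L, as.integer(round(wlen * (1 - overlap))))
  starts <- seq(1L, n - wlen + 1L, by = hop)
  w <- hann_window(wlen)
  nf <- floor(wlen / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + wlen - 1L)] * w
    acc <- acc + Mod(stats::fft(seg)[seq_len(nf)])^2
  }
  psd <- acc / length(starts) * (2 / (fs * sum(w^2)))
  psd[1L] <- psd[1L] / 2
  if (wlen %% 2 == 0) psd[nf] <- psd[nf] / 2
  list(freqs = (seq_len(nf) - 1L) * fs / wlen, psd = psd)
}

#' Power spectral entropy
#'
#' Shannon entropy `H = -sum(p_i * ln p_i)` (nats) of a normalized power
#' spectrum, with `0 * ln 0 = 0`. High H means a flat, broad spectrum; low H
#' means power condensed in few bins.
#'
#' @param p non-negative spectral masses summing to 1
#' @return entropy in nats, `0 <= H <= ln(length(p))`.
#' @export
pse <- function(p) {
  if (any(p < 0)) stop("spectral masses must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("spectral masses must sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Mean power spectral entropy per class
#'
#' Per trial: Welch PSD at one channel, restricted to the analysis band and
#' normalized to unit mass, then Shannon entropy; entropies are averaged over
#' the trials of each class.
#'
#' @param e an [epochs] object
#' @param channel channel name
#' @param band length-2 analysis band in Hz (default 5-35 Hz)
#' @param classes class labels to report (default: all present)
#' @param interval optional length-2 time window in seconds (trial time) to
#'   which trials are cropped before the PSD, e.g. the imagery period;
#'   `NULL` uses the whole epoch
#' @param seg_sec,overlap forwarded to [welch_psd()]
#' @return named numeric vector of mean entropies (nats), one per class.
#' @export
pse_per_class <- function(e, channel, band = c(5, 35),
                          classes = sort(unique(e$labels)), interval = NULL,
                          seg_sec = 1, overlap = 0.5) {
  if (band[2L] > e$fs / 2) stop("band exceeds Nyquist frequency")
  if (!is.null(interval)) e <- crop_interval(e, interval[1L], interval[2L])
  j <- channel_index(e, channel)
  h <- numeric(n_trials(e))
  for (i in seq_len(n_trials(e))) {
    ps <- welch_psd(e$data[i, j, ], e$fs, seg_sec, overlap)
    sel <- ps$freqs >= band[1L] - 1e-9 & ps$freqs <= band[2L] + 1e-9
    p <- ps$psd[sel]
    h[i] <- pse(p / sum(p))
  }
  out <- vapply(classes, function(cl) mean(h[class_trials(e, cl)]), numeric(1L))
  names(out) <- as.character(classes)
  out
}

#' Spatial distribution coefficient
#'
#' Entropy over channels of the relative change in alpha-band power between a
#' task and rest: `q_i = (m_i - r_i) / r_i`, entropy computed on the
#' normalized magnitudes `|q_i| / sum |q_j|`. High values mean spatially
#' distributed activation; 0 means change confined to one channel; the
#' maximum `ln m` means identical relative change on all m channels.
#'
#' @param task per-channel mean band power during the task (`m_i`)
#' @param rest per-channel mean band power at rest (`r_i`), all `> 0`
#' @return coefficient in nats, `0 <= H <= ln(m)`.
#' @export
sdc <- function(task, rest) {
  if (length(task) != length(rest)) stop("task and rest must have one value per channel")
  if (any(rest <= 0)) stop("rest power must be > 0 on every channel")
  q <- abs((task - rest) / rest)
  if (sum(q) == 0) stop("degenerate input: no channel changes between task and rest")
  pse(q / sum(q))
}

#' Mean alpha-band PSD per channel (SDC input)
#'
#' @param e an [epochs] object
#' @param class_id task label
#' @param band frequency band in Hz
#' @param interval time window in seconds (trial time), or `NULL` for all
#' @param electrodes channel names to include
#' @return named numeric vector of mean band PSD per electrode.
#' @export
band_psd_per_channel <- function(e, class_id, band = c(8, 13), interval = NULL,
                                 electrodes = e$channels) {
  idx <- class_trials(e, class_id)
  if (!is.null(interval)) e <- crop_interval(e, interval[1L], interval[2L])
  out <- vapply(electrodes, function(ch) {
    j <- channel_index(e, ch)
    mean(vapply(idx, function(i) {
      ps <- welch_psd(e$data[i, j, ], e$fs)
      sel <- ps$freqs >= band[1L] - 1e-9 & ps$freqs <= band[2L] + 1e-9
      mean(ps$psd[sel])
    }, numeric(1L)))
  }, numeric(1L))
  names(out) <- electrodes
  out
}

#' Topography of band-averaged ERSP values
#'
#' One scalar per electrode: the ERSP value (dB) averaged over a fixed
#' frequency band and time interval, suitable for scalp maps and as SDC
#' input.
#'
#' @param e an [epochs] object
#' @param class_id task label
#' @param band length-2 frequency band in Hz (default alpha, 8-13 Hz)
#' @param interval length-2 time window in seconds (trial time)
#' @param electrodes channel names to map (default: all channels except the
#'   ocular/cerebellar set of [excluded_channels()])
#' @param baseline baseline window for the ERSP
#' @return named numeric vector, one mean dB value per electrode.
#' @export
topography <- function(e, class_id, band = c(8, 13), interval = c(3, 7),
                       electrodes = setdiff(e$channels, excluded_channels()),
                       baseline = c(0, 3)) {
  miss <- setdiff(toupper(electrodes), toupper(e$channels))
  if (length(miss)) stop("unknown electrode(s): ", paste(miss, collapse = ", "))
  freqs <- seq(band[1L], band[2L], by = 0.5)
  out <- vapply(electrodes, function(ch) {
    m <- ersp(e, class_id, ch, baseline = baseline, freqs = freqs)
    tidx <- which(m$times >= interval[1L] - 1e-9 & m$times <= interval[2L] + 1e-9)
    mean(m$values[, tidx])
  }, numeric(1L))
  names(out) <- electrodes
  out
}
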