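# Synthetic seven-class motor-imagery EEG with known ground truth.
#
# Forward model: X(t) = A S(t) + noise. Sources are band-limited stochastic
# oscillators (white noise spectrally shaped to a mu or beta band) placed at
# sensorimotor electrodes; their mixing columns are Gaussian spatial spreads
# on the 2-D layout. Event-related desynchronization is planted by
# multiplying a source's amplitude by a class-specific attenuation factor
# during the imagery window, with smooth cosine ramps. Background activity is
# i.i.d. sensor noise plus spatially correlated 1/f noise. Everything is
# deterministic for a fixed seed.

#' Default planted sources
#'
#' Nine band-limited oscillators, three per sensorimotor site (left-hand
#' area C4, right-hand area C3, midcentral foot area Cz): a lower-mu core
#' (9.5 Hz), an upper-mu flank (12 Hz) and a beta source (20 Hz). Simple
#' tasks attenuate only the mu core of their site; compound tasks also
#' attenuate the flank and beta sources, which is how the "broader ERD band"
#' of compound imagery is planted. Amplitudes are baseline RMS microvolts.
#'
#' @return data.frame with columns `name`, `channel`, `freq`, `bw`, `amp`.
#' @export
synth_sources <- function() {
  site <- function(ch) data.frame(
    name = paste0(ch, c(".mu", ".mu2", ".beta")),
    channel = ch, freq = c(9.5, 12, 20), bw = c(2, 2, 4),
    amp = c(4, 2, 2),
    # beta generators sit slightly anterior (motor) to the mu generators
    # (somatosensory); the small offsets also keep the mixing full rank
    dx = 0, dy = c(0, -0.06, 0.1), stringsAsFactors = FALSE)
  rbind(site("C3"), site("C4"), site("CZ"))
}

#' Default class-to-ERD map
#'
#' Which sources each of the seven tasks attenuates during imagery, and by
#' how much (amplitude factor in `[0, 1]`; smaller = deeper ERD). Simple
#' tasks attenuate the single contralateral (or midcentral, for feet)
#' lower-mu core. Compound tasks attenuate strictly more sources over wider
#' bands: both-hands attenuates both hand-area mu cores (right hemisphere
#' slightly weaker); hand + contralateral foot attenuates the contralateral
#' hand area across lower mu, upper mu and beta, the midcentral area across
#' the same three bands, and weakly the homolateral hand-area mu core. The
#' rest task attenuates nothing. Within each class the deepest attenuation
#' is unique, so the class's dominant source (the direction its own spatial
#' pattern recovers) is well defined.
#'
#' @return named list of 7 named numeric vectors (source name -> factor),
#'   names `LH`, `RH`, `F`, `BH`, `LH&RF`, `RH&LF`, `R` in label order 1-7.
#' @export
default_class_map <- function() {
  list(
    "LH"    = c("C4.mu" = 0.5),
    "RH"    = c("C3.mu" = 0.5),
    "F"     = c("CZ.mu" = 0.5),
    "BH"    = c("C3.mu" = 0.5, "C4.mu" = 0.6),
    "LH&RF" = c("C4.mu" = 0.45, "C4.mu2" = 0.55, "C4.beta" = 0.6,
                "CZ.mu" = 0.55, "CZ.mu2" = 0.6, "CZ.beta" = 0.65,
                "C3.mu" = 0.75),
    "RH&LF" = c("C3.mu" = 0.45, "C3.mu2" = 0.55, "C3.beta" = 0.6,
                "CZ.mu" = 0.55, "CZ.mu2" = 0.6, "CZ.beta" = 0.65,
                "C4.mu" = 0.75),
    "R"     = numeric(0))
}

#' Task names in label order
#' @return character vector of the 7 task abbreviations for labels 1-7.
#' @export
class_names <- function() c("LH", "RH", "F", "BH", "LH&RF", "RH&LF", "R")

#' Synthetic-recording configuration
#'
#' Defaults reproduce the recording geometry the package targets: 64
#' channels in a 10/20 montage, 1000 Hz acquisition, 8 s trials with the
#' imagery cue at 3 s, 7 classes x 80 trials = 560 trials.
#'
#' @param n_trials_per_class trials per class (default 80)
#' @param fs sampling rate in Hz of the generated data (default 1000;
#'   generate at 200 to emulate already-downsampled recordings cheaply)
#' @param trial_sec trial length in seconds (default 8)
#' @param cue_sec cue time in seconds (default 3; imagery window is
#'   `cue + 0.5` to `cue + 3.5` s with 0.25 s cosine ramps)
#' @param channels montage channel names (default the full 64-channel
#'   [default_layout()]); must contain every source electrode
#' @param sources source table as in [synth_sources()]
#' @param class_map class-to-ERD map as in [default_class_map()]
#' @param noise_scale overall background-noise multiplier applied to both
#'   noise components
#' @param noise_white white sensor-noise RMS per channel, microvolts
#' @param noise_pink spatially correlated 1/f background RMS per channel,
#'   microvolts; sized so the in-band floor is within roughly 10 dB of the
#'   source peaks, as in resting EEG
#' @param mixing_sd Gaussian spatial spread of mixing columns (disc units)
#' @param noise_corr spatial correlation length of the 1/f noise (disc units)
#' @param drift nonstationarity rate: per-trial log-normal source gain sd and
#'   relative mixing-matrix jitter (0 = stationary)
#' @param erd_window imagery attenuation window relative to cue, seconds
#' @param ramp_sec ramp length in seconds
#' @param seed integer seed
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_trials_per_class = 80, fs = 1000, trial_sec = 8,
                         cue_sec = 3, channels = default_layout()$name,
                         sources = synth_sources(),
                         class_map = default_class_map(), noise_scale = 1,
                         noise_white = 1.5, noise_pink = 5,
                         mixing_sd = 0.15, noise_corr = 0.4, drift = 0,
                         erd_window = c(0.5, 3.5), ramp_sec = 0.25,
                         seed = 1) {
  cfg <- list(n_trials_per_class = n_trials_per_class, fs = fs,
              trial_sec = trial_sec, cue_sec = cue_sec, channels = channels,
              sources = sources, class_map = class_map,
              noise_scale = noise_scale, noise_white = noise_white,
              noise_pink = noise_pink, mixing_sd = mixing_sd,
              noise_corr = noise_corr, drift = drift,
              erd_window = erd_window, ramp_sec = ramp_sec, seed = seed)
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (length(cfg$class_map) != 7L)
    stop("class_map must map all 7 classes")
  for (cl in cfg$class_map) {
    if (length(cl) && (any(cl < 0) || any(cl > 1)))
      stop("attenuation factors must lie in [0, 1]")
    bad <- setdiff(names(cl), cfg$sources$name)
    if (length(bad)) stop("class_map names unknown source(s): ",
                          paste(bad, collapse = ", "))
  }
  if (any(cfg$sources$freq + cfg$sources$bw / 2 >= cfg$fs / 2))
    stop("source bands must lie below the Nyquist frequency")
  miss <- setdiff(toupper(cfg$sources$channel), toupper(cfg$channels))
  if (length(miss)) stop("montage lacks source electrode(s): ",
                         paste(miss, collapse = ", "))
  if (cfg$drift < 0) stop("drift must be >= 0")
  structure(cfg, class = "synth_config")
}

#' Nonstationary variant of a configuration
#'
#' Returns the same configuration with the covariance drift rate set:
#' per-trial log-normal gains on the sources and random jitter of the mixing
#' matrix grow with `drift`; `drift = 0` reproduces the base configuration.
#'
#' @param config a `synth_config`
#' @param drift drift rate, `>= 0`
#' @return a `synth_config`.
#' @export
nonstationary_variant <- function(config, drift) {
  if (drift < 0) stop("drift must be >= 0")
  config$drift <- drift
  validate_synth_config(config)
}

# circular FFT shaping of column signals of an n x m white matrix
shape_noise <- function(z, gain) {
  n <- nrow(z)
  zf <- stats::mvfft(z) * gain
  Re(stats::mvfft(zf, inverse = TRUE)) / n
}

# mixing column: Gaussian spatial spread centred at an electrode
mixing_matrix <- function(lay, channels, sources, sd) {
  li <- match(toupper(channels), toupper(lay$name))
  if (any(is.na(li))) stop("channel(s) missing from layout: ",
                           paste(channels[is.na(li)], collapse = ", "))
  xy <- cbind(lay$x[li], lay$y[li])
  dx <- if ("dx" %in% names(sources)) sources$dx else numeric(nrow(sources))
  dy <- if ("dy" %in% names(sources)) sources$dy else numeric(nrow(sources))
  A <- sapply(seq_len(nrow(sources)), function(s) {
    ci <- match(toupper(sources$channel[s]), toupper(channels))
    d2 <- (xy[, 1L] - xy[ci, 1L] - dx[s])^2 + (xy[, 2L] - xy[ci, 2L] - dy[s])^2
    exp(-d2 / (2 * sd^2))
  })
  colnames(A) <- sources$name
  A
}

#' Generate a synthetic motor-imagery dataset
#'
#' @param config a `synth_config`
#' @return list with `epochs` (an [epochs] object) and `truth`: the mixing
#'   matrix `mixing` (channels x sources), the per-trial per-source
#'   attenuation `schedule`, `labels`, the per-class `dominant_source` (the
#'   most attenuated source of each imagery class, `NA` for rest), and the
#'   `sources` / `class_map` / `config` used.
#' @export
generate <- function(config) {
  cfg <- validate_synth_config(config)
  fs <- cfg$fs
  S <- as.integer(round(cfg$trial_sec * fs))
  C <- length(cfg$channels)
  nsrc <- nrow(cfg$sources)
  n_per <- cfg$n_trials_per_class
  Tn <- 7L * n_per
  lay <- default_layout()
  extra <- setdiff(toupper(cfg$channels), toupper(lay$name))
  if (length(extra)) stop("unknown montage channel(s): ",
                          paste(extra, collapse = ", "))
  A <- mixing_matrix(lay, cfg$channels, cfg$sources, cfg$mixing_sd)

  # per-source band gains and 1/f gain on the trial-length FFT grid
  f <- c(seq(0, floor(S / 2)), seq(-ceiling(S / 2) + 1, -1)) * (fs / S)
  src_gain <- lapply(seq_len(nsrc), function(s)
    sqrt(butter_bp_gain(f, cfg$sources$freq[s] - cfg$sources$bw[s] / 2,
                        cfg$sources$freq[s] + cfg$sources$bw[s] / 2, 4)))
  pink_gain <- 1 / sqrt(pmax(abs(f), 1))
  pink_gain[1L] <- 0

  # spatial correlation factor for the 1/f noise
  li <- match(toupper(cfg$channels), toupper(lay$name))
  xy <- cbind(lay$x[li], lay$y[li])
  D <- as.matrix(stats::dist(xy))
  K <- exp(-D / cfg$noise_corr)
  Lk <- t(chol(K + 1e-9 * diag(C)))

  # attenuation envelope support
  tt <- (seq_len(S) - 1L) / fs
  w0 <- cfg$cue_sec + cfg$erd_window[1L]
  w1 <- cfg$cue_sec + cfg$erd_window[2L]
  r <- cfg$ramp_sec
  env_shape <- function(a) {
    env <- rep(1, S)
    core <- tt >= w0 + r & tt <= w1 - r
    env[core] <- a
    up <- tt >= w0 & tt < w0 + r
    env[up] <- a + (1 - a) * (1 + cos(pi * (tt[up] - w0) / r)) / 2
    dn <- tt > w1 - r & tt <= w1
    env[dn] <- a + (1 - a) * (1 - cos(pi * (tt[dn] - (w1 - r)) / r)) / 2
    env
  }

  with_seed(cfg$seed, {
    labels <- sample(rep(1:7, each = n_per))
    data <- array(0, c(Tn, C, S))
    schedule <- matrix(1, Tn, nsrc, dimnames = list(NULL, cfg$sources$name))
    for (i in seq_len(Tn)) {
      cl <- labels[i]
      att <- cfg$class_map[[cl]]
      # sources: shaped white noise, unit RMS, attenuated during imagery
      Z <- matrix(stats::rnorm(S * nsrc), S, nsrc)
      src <- matrix(0, nsrc, S)
      gains <- rep(1, nsrc)
      if (cfg$drift > 0) gains <- exp(cfg$drift * stats::rnorm(nsrc))
      for (s in seq_len(nsrc)) {
        x <- shape_noise(Z[, s, drop = FALSE], src_gain[[s]])
        x <- x / sqrt(mean(x^2))
        a <- if (cfg$sources$name[s] %in% names(att))
          att[[cfg$sources$name[s]]] else 1
        schedule[i, s] <- a * gains[s]
        src[s, ] <- cfg$sources$amp[s] * gains[s] * x * env_shape(a)
      }
      Ai <- A
      if (cfg$drift > 0)
        Ai <- A + cfg$drift * mean(abs(A)) *
          matrix(stats::rnorm(C * nsrc), C, nsrc)
      # background: white sensor noise + spatially correlated 1/f
      white <- matrix(stats::rnorm(C * S), C, S)
      pink <- t(shape_noise(matrix(stats::rnorm(S * C), S, C), pink_gain))
      pink <- pink / sqrt(mean(pink^2))
      data[i, , ] <- Ai %*% src +
        cfg$noise_scale * (cfg$noise_white * white +
                           cfg$noise_pink * (Lk %*% pink))
    }
    dominant <- vapply(cfg$class_map, function(att) {
      if (!length(att)) NA_integer_
      else match(names(att)[which.min(att)], cfg$sources$name)
    }, integer(1L))
    list(epochs = epochs(data, labels, fs, cfg$channels, t0 = 0),
         truth = list(mixing = A, schedule = schedule, labels = labels,
                      dominant_source = dominant, sources = cfg$sources,
                      class_map = cfg$class_map, config = cfg))
  })
}
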