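test_that("tf_power: pure tone peaks at its bin, zero signal gives zero", {
  fs <- 200
  t <- seq_len(8 * fs) / fs
  tf <- tf_power(sin(2 * pi * 10 * t), fs)
  interior <- tf$times > 1 & tf$times < 7
  peak_bin <- apply(tf$power[, interior], 2L, which.max)
  expect_true(all(abs(tf$freqs[peak_bin] - 10) <= 0.5))

  tf0 <- tf_power(numeric(400), fs)
  expect_true(all(tf0$power == 0))
  expect_error(tf_power(numeric(50), fs, window_sec = 0.5), "longer than")
})

test_that("tf_power of white noise is flat and matches the periodogram", {
  fs <- 200
  x <- withr::with_seed(5, rnorm(200 * fs, sd = 2))
  tf <- tf_power(x, fs)
  avg <- rowMeans(tf$power)
  # flat across 1-35 Hz within 20% of the band mean
  expect_true(all(abs(avg / mean(avg) - 1) < 0.2))
  # absolute level matches the raw periodogram (one-sided density)
  pg <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          fast = FALSE, detrend = FALSE, plot = FALSE)
  sel <- pg$freq >= 1 & pg$freq <= 35
  expect_lt(abs(mean(avg) / (2 * mean(pg$spec[sel])) - 1), 0.2)
})

test_that("ersp: single-trial map is baseline-normalized power; white noise is ~0 dB", {
  fs <- 100
  e <- random_epochs(n_per = 1, n_ch = 1, n_s = 8 * fs, fs = fs,
                     classes = 1, seed = 2)
  m <- ersp(e, 1, "ch1")
  tf <- tf_power(e$data[1, 1, ], fs)
  bidx <- tf$times <= 3
  bp <- rowMeans(tf$power[, bidx])
  expect_equal(m$values, 10 * log10(tf$power / bp), tolerance = 1e-12)
  expect_equal(m$n_trials, 1L)

  # stationary white noise, many trials: no event-related change anywhere
  e2 <- random_epochs(n_per = 400, n_ch = 1, n_s = 8 * fs, fs = fs,
                      classes = 1, seed = 3)
  m2 <- ersp(e2, 1, "ch1")
  expect_lt(max(abs(m2$values)), 1)

  expect_error(ersp(e, 2, "ch1"), "no trials")
  expect_error(ersp(e, 1, "nope"), "unknown channel")
  expect_error(ersp(e, 1, "ch1", baseline = c(20, 30)), "baseline")
})

test_that("band_power_curve averages over imagery time, then subjects", {
  fs <- 100
  mk <- function(seed) ersp(random_epochs(n_per = 2, n_ch = 1, n_s = 8 * fs,
                                          fs = fs, classes = 1, seed = seed),
                            1, "ch1")
  m1 <- mk(4); m2 <- mk(5)
  c1 <- band_power_curve(list(m1), imagery = c(3, 7))
  tidx <- m1$times >= 3 & m1$times <= 7
  expect_equal(c1$values, rowMeans(m1$values[, tidx]), tolerance = 1e-12)
  # two subjects: elementwise mean of their curves
  c2 <- band_power_curve(list(m2), imagery = c(3, 7))
  both <- band_power_curve(list(m1, m2), imagery = c(3, 7))
  expect_equal(both$values, (c1$values + c2$values) / 2, tolerance = 1e-12)
  # grid mismatch is an error
  m3 <- ersp(random_epochs(n_per = 1, n_ch = 1, n_s = 8 * fs, fs = fs,
                           classes = 1, seed = 6),
             1, "ch1", freqs = seq(2, 20, by = 1))
  expect_error(band_power_curve(list(m1, m3)), "common frequency grid")
})

test_that("paired_freq_ttest matches the closed-form statistic", {
  withr::with_seed(8, {
    a <- matrix(rnorm(10 * 6), 10)
    b <- matrix(rnorm(10 * 6), 10)
  })
  res <- paired_freq_ttest(a, b)
  d <- a - b
  t_ref <- colMeans(d) / (apply(d, 2, sd) / sqrt(nrow(d)))
  expect_equal(res$t, t_ref, tolerance = 1e-10)
  p_ref <- 2 * pt(-abs(t_ref), df = nrow(d) - 1)
  expect_equal(res$p, p_ref, tolerance = 1e-10)

  # identical conditions: t = 0, nothing significant
  same <- paired_freq_ttest(a, a)
  expect_true(all(same$t == 0))
  expect_true(all(!same$sig))

  # large constant shift with tiny variance: everything significant
  shift <- paired_freq_ttest(a + 100, a + matrix(rnorm(60, sd = 1e-3), 10))
  expect_true(all(shift$sig))

  expect_error(paired_freq_ttest(a, b[1:5, ]), "mismatched")
  expect_error(paired_freq_ttest(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               ">= 2 subjects")
})

test_that("pse attains its closed-form bounds", {
  expect_equal(pse(rep(1 / 61, 61)), log(61), tolerance = 1e-12)
  expect_equal(pse(c(1, rep(0, 10))), 0)
  expect_equal(pse(c(0.5, 0.5, 0, 0)), log(2), tolerance = 1e-12)
  expect_error(pse(c(-0.1, 1.1)), "non-negative")
  expect_error(pse(c(0.3, 0.3)), "sum to 1")
})

test_that("pse is permutation-invariant and bounded", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      p <- runif(17); p <- p / sum(p)
      h <- pse(p)
      expect_gte(h, 0); expect_lte(h, log(17) + 1e-12)
      expect_equal(pse(sample(p)), h, tolerance = 1e-12)
    }
  })
})

test_that("pse_per_class: identical trials, white-noise level, broader ERD", {
  fs <- 100
  # identical trials: class mean equals the single-trial value
  x <- withr::with_seed(13, rnorm(4 * fs))
  e <- epochs(array(rep(x, each = 2), c(2, 1, 4 * fs)), c(1L, 1L), fs, "ch1")
  v <- pse_per_class(e, "ch1", band = c(5, 35))
  ps <- welch_psd(x, fs)
  sel <- ps$freqs >= 5 & ps$freqs <= 35
  expect_equal(unname(v["1"]), pse(ps$psd[sel] / sum(ps$psd[sel])),
               tolerance = 1e-12)

  # white noise: mean entropy within 2% of the uniform maximum
  e2 <- random_epochs(n_per = 40, n_ch = 1, n_s = 8 * fs, fs = fs,
                      classes = 1, seed = 14)
  v2 <- pse_per_class(e2, "ch1", band = c(5, 35))
  n_bins <- sum(ps$freqs >= 5 & ps$freqs <= 35)
  expect_lt(abs(v2[["1"]] / log(n_bins) - 1), 0.02)

  # broader attenuation of a peaked base spectrum raises the entropy
  base <- c(rep(0.5, 4), rep(5, 3), rep(0.5, 6), rep(2, 5), rep(0.5, 13))
  narrow <- base; narrow[5:7] <- narrow[5:7] * 0.25
  broad <- narrow; broad[14:18] <- broad[14:18] * 0.36
  expect_gt(pse(broad / sum(broad)), pse(narrow / sum(narrow)))
})

test_that("sdc matches closed forms and validates input", {
  m <- 5
  rest <- rep(2, m)
  # identical relative change on all channels: ln m
  expect_equal(sdc(rest * 1.5, rest), log(m), tolerance = 1e-12)
  # change confined to one channel: 0
  task <- rest; task[3] <- 4
  expect_equal(sdc(task, rest), 0)
  # hand-computed two-channel case: |q| = (3, 1)
  expect_equal(sdc(c(4, 2), c(1, 1)), -0.75 * log(0.75) - 0.25 * log(0.25),
               tolerance = 1e-10)
  # ERD (negative q) uses magnitudes: same value as the ERS mirror image
  expect_equal(sdc(c(1 - 0.3, 1 - 0.1), c(1, 1)),
               sdc(c(1.3, 1.1), c(1, 1)), tolerance = 1e-12)
  expect_error(sdc(c(1, 2), c(1, 0)), "> 0")
  expect_error(sdc(c(1, 2), c(1, 2, 3)), "per channel")
  expect_error(sdc(c(1, 2), c(1, 2)), "degenerate")
})

test_that("sdc is permutation-invariant over channels", {
  withr::with_seed(15, {
    task <- runif(8, 0.5, 2); rest <- runif(8, 0.5, 2)
    h <- sdc(task, rest)
    perm <- sample(8)
    expect_equal(sdc(task[perm], rest[perm]), h, tolerance = 1e-12)
  })
})

test_that("relative measures are invariant to global amplitude scaling", {
  fs <- 100
  e <- random_epochs(n_per = 3, n_ch = 2, n_s = 8 * fs, fs = fs,
                     classes = 1:2, seed = 16)
  e_scaled <- e; e_scaled$data <- e$data * 7.7
  expect_equal(ersp(e_scaled, 1, "ch1")$values, ersp(e, 1, "ch1")$values,
               tolerance = 1e-10)
  expect_equal(pse_per_class(e_scaled, "ch1"), pse_per_class(e, "ch1"),
               tolerance = 1e-10)
  t1 <- band_psd_per_channel(e, 1, electrodes = e$channels)
  r1 <- band_psd_per_channel(e, 2, electrodes = e$channels)
  expect_equal(sdc(t1 * 7.7^2, r1 * 7.7^2), sdc(t1, r1), tolerance = 1e-10)
})

test_that("topography returns one value per scalp electrode", {
  fs <- 100
  # spatially uniform data: all electrode values equal
  x <- withr::with_seed(17, rnorm(4 * fs))
  e <- epochs(array(rep(x, each = 3), c(1, 3, 4 * fs)),
              1L, fs, c("C3", "CZ", "C4"))
  tp <- topography(e, 1, interval = c(3, 4), electrodes = e$channels)
  expect_equal(length(tp), 3L)
  expect_lt(max(tp) - min(tp), 1e-10)
  expect_error(topography(e, 1, electrodes = c("C3", "XX")), "unknown")
  # the default electrode set excludes HEO/VEO/CB1/CB2: 60 of 64
  expect_equal(length(setdiff(default_layout()$name, excluded_channels())),
               60L)
})
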