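toy_cs <- function() covariance_set(list(diag(c(2, 1)), diag(c(1, 2))))

test_that("trial_covariance is trace-normalized, symmetric, PSD", {
  x <- withr::with_seed(1, matrix(rnorm(4 * 100), 4))
  cv <- trial_covariance(x)
  expect_equal(sum(diag(cv)), 1, tolerance = 1e-12)
  expect_symmetric_psd(cv)
  # rank-1 trial: single active channel
  x1 <- matrix(0, 3, 50); x1[2, ] <- rnorm(50)
  cv1 <- suppressWarnings(trial_covariance(x1))
  expect_equal(cv1[2, 2], 1, tolerance = 1e-12)
  expect_equal(sum(abs(cv1)) - cv1[2, 2], 0, tolerance = 1e-12)
  # isotropic limit: long white trial approaches I/N
  xw <- withr::with_seed(2, matrix(rnorm(4 * 20000), 4))
  expect_lt(max(abs(trial_covariance(xw) - diag(4) / 4)), 0.02)
  expect_error(trial_covariance(matrix(0, 3, 50)), "zero-energy")
  expect_warning(trial_covariance(matrix(rnorm(12), 4, 3)), "rank-deficient")
})

test_that("class_covariances averages trials per class and sums classes", {
  e <- random_epochs(n_per = 3, n_ch = 4, n_s = 80, classes = 1:3, seed = 3)
  cs <- class_covariances(e, shrinkage = 0)
  for (j in seq_along(cs$classes)) {
    idx <- which(e$labels == cs$classes[j])
    man <- Reduce(`+`, lapply(idx, function(i)
      trial_covariance(trial_matrix(e, i)))) / length(idx)
    expect_equal(cs$sigmas[[j]], (man + t(man)) / 2, tolerance = 1e-12)
  }
  expect_equal(cs$sigma, Reduce(`+`, cs$sigmas), tolerance = 1e-12)
  # single trial per class: class mean is that trial's covariance
  e1 <- suppressWarnings({
    ee <- random_epochs(n_per = 1, n_ch = 3, n_s = 40, classes = 1:2, seed = 4)
    class_covariances(ee, shrinkage = 0)
  })
  expect_equal(length(e1$trial_covs[[1L]]), 1L)
  expect_equal(e1$sigmas[[1L]], e1$trial_covs[[1L]][[1L]], tolerance = 1e-12)
  # missing class is an error; shrinkage keeps the composite PD after CAR
  expect_error(class_covariances(e, classes = 1:7), "no trials")
  ec <- common_average_reference(
    random_epochs(n_per = 4, n_ch = 5, n_s = 100, classes = 1:2, seed = 5))
  cs2 <- class_covariances(ec)
  expect_gt(min(eigen(cs2$sigma, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
})

test_that("whitening satisfies P Sigma P' = I and diagonal closed forms", {
  # diagonal closed form
  wh <- whitening(covariance_set(list(diag(c(4, 1)))))
  expect_equal(abs(wh$P), diag(c(0.5, 1)), tolerance = 1e-12)
  expect_equal(wh$lambda, c(4, 1))
  # identity: P is orthogonal and whitens exactly (the eigenbasis of a
  # degenerate spectrum is an arbitrary orthonormal basis)
  wh_i <- whitening(covariance_set(list(diag(2))))
  expect_lt(max(abs(crossprod(wh_i$P) - diag(2))), 1e-12)
  expect_equal(wh_i$lambda, c(1, 1))
  # random SPD
  s <- random_spd(6, seed = 6)
  wh6 <- whitening(covariance_set(list(s)))
  expect_lt(max(abs(wh6$P %*% s %*% t(wh6$P) - diag(6))), 1e-8)
  expect_true(all(diff(wh6$lambda) <= 0))
  # rank-deficient composite advises shrinkage
  expect_error(whitening(covariance_set(list(diag(c(1, 0))))), "shrinkage")
})

test_that("multi_csp: diagonal toy, indistinguishable classes, identities", {
  fb <- multi_csp(toy_cs())
  expect_equal(fb$eigenvalues[[1L]], c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(fb$eigenvalues[[2L]], c(2 / 3, 1 / 3), tolerance = 1e-10)
  # top filter of class 1 selects channel 1
  w1 <- fb$W[[1L]][1L, ]
  expect_gt(abs(w1[1L]) / abs(w1[2L] + 1e-300), 1e6)

  # equal class covariances: every eigenvalue is 1/n_classes
  s <- random_spd(4, seed = 7)
  cs_eq <- covariance_set(rep(list(s), 7))
  fb_eq <- multi_csp(cs_eq)
  for (ev in fb_eq$eigenvalues)
    expect_equal(ev, rep(1 / 7, 4), tolerance = 1e-8)

  # random SPD set: W Sigma W' = I and W Sigma_i W' diagonal
  cs_r <- withr::with_seed(8, covariance_set(lapply(1:3, function(i) random_spd(5))))
  fb_r <- multi_csp(cs_r)
  for (i in 1:3) {
    W <- fb_r$W[[i]]
    expect_lt(max(abs(W %*% cs_r$sigma %*% t(W) - diag(5))), 1e-8)
    y <- W %*% cs_r$sigmas[[i]] %*% t(W)
    expect_lt(max(abs(y - diag(diag(y)))), 1e-8)
    expect_equal(diag(y), fb_r$eigenvalues[[i]], tolerance = 1e-8)
  }
})

test_that("complementarity: class and rest eigenvalue spectra sum to one", {
  cs <- withr::with_seed(9, covariance_set(lapply(1:4, function(i) random_spd(6))))
  wh <- whitening(cs)
  fb <- multi_csp(cs)
  for (i in 1:4) {
    rest <- cs$sigma - cs$sigmas[[i]]
    W <- fb$W[[i]]
    y_rest <- W %*% rest %*% t(W)
    expect_equal(fb$eigenvalues[[i]] + diag(y_rest), rep(1, 6),
                 tolerance = 1e-8)
    expect_lt(max(abs(y_rest - diag(diag(y_rest)))), 1e-8)
  }
})

test_that("gecsp: diagonal toy, trace identity, eigenvalues in [0, 1]", {
  fb <- gecsp(toy_cs())
  expect_equal(fb$eigenvalues[[1L]], c(2 / 3, 1 / 3), tolerance = 1e-10)
  w1 <- fb$W[[1L]][1L, ]
  expect_gt(abs(w1[1L]) / abs(w1[2L] + 1e-300), 1e6)
  cs <- withr::with_seed(10, covariance_set(lapply(1:3, function(i) random_spd(5))))
  wh <- whitening(cs)
  fb_r <- gecsp(cs)
  for (i in 1:3) {
    ev <- fb_r$eigenvalues[[i]]
    expect_true(all(ev >= -1e-10 & ev <= 1 + 1e-10))
    expect_equal(sum(ev),
                 sum(diag(wh$P %*% cs$sigmas[[i]] %*% t(wh$P))),
                 tolerance = 1e-8)
  }
})

test_that("multi_csp and gecsp agree on 100 random SPD sets (N <= 8)", {
  withr::with_seed(20, {
    for (rep in 1:100) {
      n <- sample(2:8, 1)
      k <- sample(2:7, 1)
      cs <- covariance_set(lapply(seq_len(k), function(i) random_spd(n)))
      f1 <- multi_csp(cs); f2 <- gecsp(cs)
      for (i in seq_len(k)) {
        expect_lt(max(abs(f1$eigenvalues[[i]] - f2$eigenvalues[[i]])), 1e-6)
        # filters match up to sign/scale: both are Sigma-orthonormal and
        # sign-fixed, so they match elementwise up to the eigen solver's
        # tolerance (generic spectra have no degenerate eigenvalues)
        expect_lt(max(abs(f1$W[[i]] - f2$W[[i]])), 1e-5)
      }
    }
  })
})

test_that("stationarity penalty: stationary class is 0, signed toy, PSD", {
  s <- random_spd(3, seed = 21)
  cs <- covariance_set(list(s, s), trial_covs = list(list(s, s, s), list(s)))
  expect_equal(stationarity_penalty(cs, 1), matrix(0, 3, 3),
               tolerance = 1e-10)
  expect_warning(p2 <- stationarity_penalty(cs, 2), "single trial")
  expect_equal(p2, matrix(0, 3, 3))

  # two trials deviating by +/- diag(1, -1): each |Delta| = I, sum = 2I
  m <- diag(c(2, 2))
  d <- diag(c(1, -1))
  cs2 <- covariance_set(list(m), trial_covs = list(list(m + d, m - d)))
  expect_equal(stationarity_penalty(cs2, 1), 2 * diag(2), tolerance = 1e-10)

  # random trial covariances: penalty symmetric PSD
  tcs <- withr::with_seed(22, lapply(1:6, function(i) random_spd(4)))
  cs3 <- covariance_set(list(Reduce(`+`, tcs) / 6), trial_covs = list(tcs))
  expect_symmetric_psd(stationarity_penalty(cs3, 1))
})

test_that("strcsp: reduces to gecsp at (0,0), diagonal toy, beta limit", {
  cs <- withr::with_seed(23, covariance_set(lapply(1:3, function(i) random_spd(5))))
  f0 <- strcsp(cs, 0, 0)
  fg <- gecsp(cs)
  for (i in 1:3) {
    expect_equal(f0$eigenvalues[[i]], fg$eigenvalues[[i]], tolerance = 1e-10)
    expect_equal(f0$W[[i]], fg$W[[i]], tolerance = 1e-10)
  }

  # toy: penalty_1 = I, alpha = 1, beta = 0 -> eigenvalues {0.5, 0.25}
  ft <- strcsp(toy_cs(), 1, 0, penalties = list(diag(2), diag(2)))
  expect_equal(ft$eigenvalues[[1L]], c(0.5, 0.25), tolerance = 1e-10)

  # beta -> infinity: top filter approaches the principal eigenvector of
  # Sigma_i (denominator dominated by beta I)
  fbig <- strcsp(cs, 0, 1e6)
  for (i in 1:3) {
    u1 <- eigen(cs$sigmas[[i]], symmetric = TRUE)$vectors[, 1L]
    w1 <- fbig$W[[i]][1L, ]
    expect_gt(abs(sum(u1 * w1)) / sqrt(sum(w1^2)), 1 - 1e-6)
  }
  expect_error(strcsp(cs, -1, 0), ">= 0")
})

test_that("filter norm is non-increasing in beta (Tikhonov monotonicity)", {
  cs <- withr::with_seed(24, covariance_set(lapply(1:3, function(i) random_spd(6))))
  betas <- c(0, 0.1, 1, 10, 100)
  norms <- vapply(betas, function(b)
    sqrt(sum(strcsp(cs, 0, b)$W[[1L]][1L, ]^2)), numeric(1L))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("scale invariance: scaling all trials leaves filters unchanged", {
  e <- random_epochs(n_per = 4, n_ch = 4, n_s = 100, classes = 1:3, seed = 25)
  e2 <- e; e2$data <- e$data * 31.4
  f1 <- multi_csp(class_covariances(e))
  f2 <- multi_csp(class_covariances(e2))
  for (i in seq_along(f1$W))
    expect_equal(f1$W[[i]], f2$W[[i]], tolerance = 1e-8)
})

test_that("spatial patterns invert the filters", {
  cs <- withr::with_seed(26, covariance_set(lapply(1:3, function(i) random_spd(5))))
  fb <- multi_csp(cs)
  pats <- spatial_patterns(fb)
  for (i in 1:3)
    expect_lt(max(abs(pats[[i]] %*% fb$W[[i]] - diag(5))), 1e-8)
  # orthonormal filters on composite Sigma = I: patterns equal W'
  csI <- covariance_set(list(diag(4) / 2, diag(4) / 2))
  fbI <- multi_csp(csI)
  pI <- spatial_patterns(fbI)
  expect_equal(pI[[1L]], t(fbI$W[[1L]]), tolerance = 1e-10)
})

test_that("filter banks round-trip through the HDF5 container", {
  cs <- withr::with_seed(27, covariance_set(lapply(1:3, function(i) random_spd(4))))
  fb <- strcsp(cs, 0.5, 0.25,
               penalties = withr::with_seed(28, lapply(1:3, function(i) {
                 p <- random_spd(4); p
               })))
  path <- withr::local_tempfile(fileext = ".h5")
  save_filter_bank(fb, path)
  fb2 <- load_filter_bank(path)
  expect_equal(fb2$method, "strcsp")
  expect_equal(fb2$alpha, 0.5)
  expect_equal(fb2$beta, 0.25)
  for (i in 1:3) {
    expect_equal(fb2$W[[i]], fb$W[[i]], tolerance = 1e-12)
    expect_equal(fb2$eigenvalues[[i]], fb$eigenvalues[[i]], tolerance = 1e-12)
  }
})
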