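# One-versus-rest multi-class common spatial patterns.
#
# Three variants over a shared covariance structure:
#   multi_csp  — whiten the composite covariance, then eigendecompose each
#                whitened class covariance (joint-diagonalization route);
#   gecsp      — solve the generalized eigenproblem (Sigma_i, Sigma) directly
#                via a Cholesky reduction (an algebraically equivalent but
#                numerically independent route);
#   strcsp     — gecsp with the denominator augmented by a per-class
#                stationarity penalty (weight alpha) and a Tikhonov identity
#                penalty (weight beta).
# Filters are rows of W, sorted by descending eigenvalue, sign-fixed so the
# largest-magnitude entry is positive, and scaled so W B W' = I where B is
# the denominator matrix of the variant.

sym <- function(m) (m + t(m)) / 2

# matrix absolute value: flip negative eigenvalues positive
mat_abs <- function(m) {
  em <- eigen(sym(m), symmetric = TRUE)
  sym(em$vectors %*% (abs(em$values) * t(em$vectors)))
}

#' Trace-normalized trial covariance
#'
#' `X X' / trace(X X')`: symmetric, positive semi-definite, unit trace, so
#' spatial filters are invariant to global amplitude scaling.
#'
#' @param x channels x samples matrix of one trial
#' @return channels x channels covariance matrix with unit trace.
#' @export
trial_covariance <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) <= nrow(x))
    warning("trial has no more samples (", ncol(x), ") than channels (",
            nrow(x), "); covariance estimate is rank-deficient")
  tr <- sum(x * x)
  if (tr == 0) stop("zero-energy trial")
  tcrossprod(x) / tr
}

#' Construct a covariance set from explicit matrices
#'
#' Mainly for closed-form toys and tests; [class_covariances()] builds the
#' same structure from epoched data.
#'
#' @param sigmas list of per-class mean covariance matrices (all N x N)
#' @param trial_covs optional list (per class) of lists of per-trial
#'   covariance matrices, required by [stationarity_penalty()]
#' @param classes class labels, parallel to `sigmas`
#' @return a `covariance_set` object: list with `sigmas`, `sigma` (their
#'   sum), `sigmas_raw`, `trial_covs`, `classes`, `n_channels`.
#' @export
covariance_set <- function(sigmas, trial_covs = NULL,
                           classes = seq_along(sigmas)) {
  n <- nrow(sigmas[[1L]])
  for (s in sigmas) {
    if (!is.matrix(s) || nrow(s) != n || ncol(s) != n)
      stop("all class covariances must be square matrices of equal size")
    if (max(abs(s - t(s))) > 1e-8) stop("class covariance not symmetric")
  }
  structure(list(sigmas = sigmas, sigma = sym(Reduce(`+`, sigmas)),
                 sigmas_raw = sigmas, trial_covs = trial_covs,
                 classes = classes, n_channels = n),
            class = "covariance_set")
}

#' Per-class and composite covariance structure
#'
#' For each class: the arithmetic mean of the trace-normalized trial
#' covariances, lightly shrunk towards a scaled identity
#' (`(1 - g) S + g (tr(S)/N) I`) so the composite is positive definite even
#' after common average referencing (which removes one rank). The composite
#' covariance is the sum of the class means. Per-trial covariances are
#' retained for the stationarity penalty.
#'
#' @param e an [epochs] object
#' @param classes classes that must all be present (default: labels found)
#' @param shrinkage shrinkage weight `g` (default 1e-6)
#' @return a `covariance_set` object.
#' @export
class_covariances <- function(e, classes = sort(unique(e$labels)),
                              shrinkage = 1e-6) {
  missing_cl <- setdiff(classes, unique(e$labels))
  if (length(missing_cl))
    stop("no trials for class(es): ", paste(missing_cl, collapse = ", "))
  n <- n_channels(e)
  tc <- lapply(classes, function(cl)
    lapply(class_trials(e, cl), function(i) trial_covariance(trial_matrix(e, i))))
  raw <- lapply(tc, function(l) sym(Reduce(`+`, l) / length(l)))
  sh <- lapply(raw, function(s)
    (1 - shrinkage) * s + shrinkage * (sum(diag(s)) / n) * diag(n))
  cs <- covariance_set(sh, trial_covs = tc, classes = classes)
  cs$sigmas_raw <- raw
  cs$channels <- e$channels
  cs
}

#' Whitening of the composite covariance
#'
#' Eigendecomposes `Sigma = U0 L U0'` (eigenvalues descending) and returns
#' the whitening matrix `P = L^{-1/2} U0'` with `P Sigma P' = I`.
#'
#' @param cs a `covariance_set`
#' @param tol relative eigenvalue tolerance below which `Sigma` is treated as
#'   rank-deficient
#' @return list with `P`, `U0`, `lambda`.
#' @export
whitening <- function(cs, tol = 1e-12) {
  eg <- eigen(sym(cs$sigma), symmetric = TRUE)
  if (min(eg$values) <= tol * max(eg$values))
    stop("composite covariance is rank-deficient; increase the shrinkage in ",
         "class_covariances()")
  list(P = (1 / sqrt(eg$values)) * t(eg$vectors), U0 = eg$vectors,
       lambda = eg$values)
}

fix_signs <- function(w) {
  for (r in seq_len(nrow(w))) {
    j <- which.max(abs(w[r, ]))
    if (w[r, j] < 0) w[r, ] <- -w[r, ]
  }
  w
}

new_filter_bank <- function(W, eigenvalues, method, cs, alpha = NA_real_,
                            beta = NA_real_, denominators = NULL) {
  structure(list(W = W, eigenvalues = eigenvalues, method = method,
                 classes = cs$classes, sigmas = cs$sigmas, sigma = cs$sigma,
                 channels = cs$channels, alpha = alpha, beta = beta,
                 denominators = denominators),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> method = %s, %d classes, %d channels\n",
              x$method, length(x$W), ncol(x$W[[1L]])))
  if (!is.na(x$alpha)) cat(sprintf("alpha = %g, beta = %g\n", x$alpha, x$beta))
  invisible(x)
}

#' Multi-class CSP via whitening and joint diagonalization
#'
#' For each class i, with `P` whitening the composite covariance: the
#' whitened class covariance `Y_i = P Sigma_i P'` is eigendecomposed,
#' `Y_i = U_i L_i U_i'`, and the class filter matrix is `W_i = U_i' P`.
#' Because `Y_i + Y_i' = P Sigma P' = I` (one-versus-rest), the eigenvalue
#' spectra of a class and its rest complement are complementary.
#'
#' @param cs a `covariance_set`
#' @return a `filter_bank` with per-class `W` (filters as rows, descending
#'   eigenvalue) and `eigenvalues`.
#' @export
multi_csp <- function(cs) {
  wh <- whitening(cs)
  W <- list(); ev <- list()
  for (i in seq_along(cs$sigmas)) {
    Y <- sym(wh$P %*% cs$sigmas[[i]] %*% t(wh$P))
    eg <- eigen(Y, symmetric = TRUE)
    W[[i]] <- fix_signs(t(eg$vectors) %*% wh$P)
    ev[[i]] <- eg$values
  }
  new_filter_bank(W, ev, "multi_csp", cs,
                  denominators = rep(list(cs$sigma), length(cs$sigmas)))
}

# generalized symmetric-definite eigenproblem A v = lambda B v via Cholesky;
# eigenvectors scaled so V' B V = I, eigenvalues descending
gen_eig <- function(A, B) {
  R <- chol(sym(B))                     # B = R' R
  Rt <- t(R)
  C <- forwardsolve(Rt, t(forwardsolve(Rt, sym(A))))
  eg <- eigen(sym(C), symmetric = TRUE)
  list(values = eg$values, vectors = backsolve(R, eg$vectors))
}

#' Multi-class CSP via the generalized eigenproblem
#'
#' Maximizes the Rayleigh quotient `(W' Sigma_i W) / (W' Sigma W)` per class
#' by solving `Sigma_i W = lambda Sigma W`. Algebraically equivalent to
#' [multi_csp()] (identical eigenvalue spectra, filters equal up to sign);
#' computed by an independent Cholesky reduction.
#'
#' @param cs a `covariance_set`
#' @return a `filter_bank`.
#' @export
gecsp <- function(cs) {
  W <- list(); ev <- list()
  for (i in seq_along(cs$sigmas)) {
    ge <- gen_eig(cs$sigmas[[i]], cs$sigma)
    W[[i]] <- fix_signs(t(ge$vectors))
    ev[[i]] <- ge$values
  }
  new_filter_bank(W, ev, "gecsp", cs,
                  denominators = rep(list(cs$sigma), length(cs$sigmas)))
}

#' Stationarity penalty matrix of one class
#'
#' Sums, over the trials of the class, the matrix absolute value of the
#' deviation of each trial covariance from the class mean
#' (`abs_m(Sigma_ik - Sigma_i)`, negative eigenvalues flipped positive).
#' The result is a symmetric PSD matrix whose quadratic form `w' D w` bounds
#' the across-trial fluctuation of the filtered variance; as printed without
#' the absolute value the signed deviations would cancel in expectation.
#'
#' @param cs a `covariance_set` built with per-trial covariances
#' @param class_id class label
#' @return N x N symmetric positive semi-definite `penalty_matrix`.
#' @export
stationarity_penalty <- function(cs, class_id) {
  i <- match(class_id, cs$classes)
  if (is.na(i)) stop("class ", class_id, " not in covariance set")
  if (is.null(cs$trial_covs))
    stop("covariance set carries no per-trial covariances")
  tc <- cs$trial_covs[[i]]
  n <- cs$n_channels
  if (length(tc) < 2L) {
    warning("class ", class_id, " has a single trial; stationarity penalty is 0")
    return(matrix(0, n, n))
  }
  m <- sym(Reduce(`+`, tc) / length(tc))
  Reduce(`+`, lapply(tc, function(ck) mat_abs(ck - m)))
}

#' Stationary Tikhonov-regularized multi-class CSP
#'
#' Per class i, maximizes
#' `(W' Sigma_i W) / (W' (Sigma + alpha * D_i + beta * I) W)` where `D_i` is
#' the class stationarity penalty and the identity term is the Tikhonov
#' penalty on the filter norm. `strcsp(cs, 0, 0)` reduces exactly to
#' [gecsp()].
#'
#' @param cs a `covariance_set` (with per-trial covariances when `alpha > 0`)
#' @param alpha stationarity penalty weight, `>= 0`
#' @param beta Tikhonov penalty weight, `>= 0`
#' @param penalties optional list of precomputed per-class penalty matrices
#'   (as from [stationarity_penalty()]); computed from `cs` when missing
#' @param penalty_scope `"target"` (default) penalizes each class bank with
#'   its own class's penalty; `"pooled"` with the sum over all classes
#' @return a `filter_bank` with `alpha`, `beta` recorded.
#' @export
strcsp <- function(cs, alpha, beta, penalties = NULL,
                   penalty_scope = c("target", "pooled")) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  penalty_scope <- match.arg(penalty_scope)
  n <- cs$n_channels
  if (alpha > 0 && is.null(penalties))
    penalties <- lapply(cs$classes, function(cl) stationarity_penalty(cs, cl))
  if (alpha > 0 && penalty_scope == "pooled") {
    pooled <- Reduce(`+`, penalties)
    penalties <- rep(list(pooled), length(cs$sigmas))
  }
  W <- list(); ev <- list(); dens <- list()
  for (i in seq_along(cs$sigmas)) {
    B <- cs$sigma + beta * diag(n)
    if (alpha > 0) B <- B + alpha * penalties[[i]]
    ge <- gen_eig(cs$sigmas[[i]], B)
    W[[i]] <- fix_signs(t(ge$vectors))
    ev[[i]] <- ge$values
    dens[[i]] <- B
  }
  new_filter_bank(W, ev, "strcsp", cs, alpha = alpha, beta = beta,
                  denominators = dens)
}

#' Index of the most discriminative filter of a class bank
#'
#' Eigenvalues are sorted descending; the uninformative level of a
#' one-vs-rest bank is `1 / n_classes` (a direction with identical variance
#' share in every class). The most discriminative filter is the one whose
#' eigenvalue lies farthest from that level on a log scale. For classes
#' whose planted effect is an ERD (power attenuation) this is typically the
#' LAST filter: the attenuated direction carries less variance than the rest
#' average.
#'
#' @param fb a `filter_bank`
#' @param class_id class label
#' @return integer filter index into the class's rows of `W`.
#' @export
most_discriminative <- function(fb, class_id) {
  i <- match(class_id, fb$classes)
  if (is.na(i)) stop("class ", class_id, " not in filter bank")
  ev <- pmax(fb$eigenvalues[[i]], .Machine$double.eps)
  which.max(abs(log(ev) - log(1 / length(fb$classes))))
}

#' Spatial patterns of a filter bank
#'
#' The pattern associated with filter row j is column j of the (pseudo-)
#' inverse of the filter matrix: `A_i = Sigma W_i' (W_i Sigma W_i')^{-1}`,
#' which equals `W_i^{-1}` for a full invertible bank. Patterns are the
#' scalp-interpretable mixing columns corresponding to each filter.
#'
#' @param fb a `filter_bank`
#' @return list of per-class N x k pattern matrices (patterns as columns).
#' @export
spatial_patterns <- function(fb) {
  lapply(fb$W, function(w) {
    g <- w %*% fb$sigma %*% t(w)
    if (rcond(g) < 1e-12) {
      warning("near-singular filtered covariance; using pseudo-inverse")
      gi <- MASS_ginv(g)
    } else gi <- solve(g)
    fb$sigma %*% t(w) %*% gi
  })
}

# small Moore-Penrose pseudo-inverse (avoids a MASS dependency)
MASS_ginv <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Save / load a filter bank in HDF5
#'
#' Layout: `/filters/class_<i>`, `/patterns/class_<i>`,
#' `/eigenvalues/class_<i>`, `/method`, `/classes`, `/alpha`, `/beta`.
#'
#' @param fb a `filter_bank`
#' @param path file path
#' @return `save_filter_bank()` returns `path` invisibly; `load_filter_bank()`
#'   a `filter_bank` (without denominators; patterns recomputable only if
#'   saved).
#' @export
save_filter_bank <- function(fb, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "filters")
  rhdf5::h5createGroup(path, "eigenvalues")
  rhdf5::h5createGroup(path, "patterns")
  pats <- spatial_patterns(fb)
  for (i in seq_along(fb$W)) {
    cl <- fb$classes[i]
    rhdf5::h5write(fb$W[[i]], path, paste0("filters/class_", cl))
    rhdf5::h5write(fb$eigenvalues[[i]], path, paste0("eigenvalues/class_", cl))
    rhdf5::h5write(pats[[i]], path, paste0("patterns/class_", cl))
  }
  rhdf5::h5write(fb$method, path, "method")
  rhdf5::h5write(as.integer(fb$classes), path, "classes")
  rhdf5::h5write(fb$sigma, path, "sigma")
  rhdf5::h5write(ifelse(is.na(fb$alpha), -1, fb$alpha), path, "alpha")
  rhdf5::h5write(ifelse(is.na(fb$beta), -1, fb$beta), path, "beta")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_filter_bank
#' @export
load_filter_bank <- function(path) {
  classes <- as.integer(rhdf5::h5read(path, "classes"))
  W <- lapply(classes, function(cl)
    rhdf5::h5read(path, paste0("filters/class_", cl)))
  ev <- lapply(classes, function(cl)
    as.numeric(rhdf5::h5read(path, paste0("eigenvalues/class_", cl))))
  a <- as.numeric(rhdf5::h5read(path, "alpha"))
  b <- as.numeric(rhdf5::h5read(path, "beta"))
  fb <- structure(list(W = W, eigenvalues = ev,
                       method = as.character(rhdf5::h5read(path, "method")),
                       classes = classes, sigmas = NULL,
                       sigma = rhdf5::h5read(path, "sigma"), channels = NULL,
                       alpha = ifelse(a < 0, NA_real_, a),
                       beta = ifelse(b < 0, NA_real_, b),
                       denominators = NULL),
                  class = "filter_bank")
  rhdf5::h5closeAll()
  fb
}
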