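# Log-variance features, linear SVM and cross-validated evaluation.
#
# The classifier is a linear support vector machine trained by dual
# coordinate descent (compiled, see src/), multi-class by one-vs-one voting
# (the LIBSVM scheme) or optionally one-vs-rest. Features are standardized
# with training-set statistics inside the model, so no information leaks
# from test folds.

# run code with a private, restored RNG state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Log-variance features under a filter bank
#'
#' For every trial, the top-`k` spatial filters of each class bank are
#' applied and the natural log of the variance of each filtered time series
#' is taken, giving `n_classes * k` features per trial. Epochs are expected
#' to be band-pass filtered (8-30 Hz) and cropped to the imagery window
#' before feature extraction.
#'
#' @param e an [epochs] object
#' @param fb a `filter_bank`
#' @param k number of filters per class bank, `1 <= k <= N`
#' @param filter_ends `"both"` (default) takes the `k` filters whose
#'   eigenvalues are most extreme, alternating between the top (largest
#'   eigenvalue) and bottom (smallest) of each class bank — for
#'   one-vs-rest banks an ERD class's own information sits at the bottom
#'   end; `"top"` takes the first `k` filters only
#' @return a `feature_matrix`: trials x (n_classes * k) numeric matrix with
#'   attributes `labels`, `method`, `k`, `alpha`, `beta`.
#' @export
log_variance_features <- function(e, fb, k, filter_ends = c("both", "top")) {
  filter_ends <- match.arg(filter_ends)
  kmax <- min(vapply(fb$W, nrow, integer(1L)))
  if (k < 1L || k > kmax)
    stop("k must be between 1 and the available ", kmax, " filters per class")
  W_all <- w_top_k(fb, k, filter_ends)
  S <- n_samples(e)
  out <- matrix(NA_real_, n_trials(e), nrow(W_all))
  for (i in seq_len(n_trials(e))) {
    z <- W_all %*% trial_matrix(e, i)
    v <- rowSums((z - rowMeans(z))^2) / (S - 1L)
    out[i, ] <- log(pmax(v, 1e-300))  # clamp: CAR can zero one direction
  }
  colnames(out) <- paste0("c", rep(fb$classes, each = k), ".f", seq_len(k))
  structure(out, labels = e$labels, method = fb$method, k = k,
            alpha = fb$alpha, beta = fb$beta, class = "feature_matrix")
}

#' Stratified cross-validation folds
#'
#' Partitions trials into `n_folds` class-stratified folds: with 80 trials
#' per class and 10 folds, every fold holds exactly 8 trials of each class.
#' Deterministic for a fixed seed.
#'
#' @param labels per-trial class labels
#' @param n_folds number of folds
#' @param seed integer seed
#' @return integer vector of fold assignments in `1..n_folds`.
#' @export
make_folds <- function(labels, n_folds = 10, seed = 1) {
  counts <- table(labels)
  if (n_folds > min(counts))
    stop("n_folds (", n_folds, ") exceeds the smallest class count (",
         min(counts), ")")
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == as.integer(cl)))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Train a linear SVM
#'
#' L2-regularized hinge-loss linear SVM solved by dual coordinate descent,
#' multi-class by one-vs-one voting (default) or one-vs-rest. Features are
#' standardized with training statistics stored in the model.
#'
#' @param x trials x features numeric matrix
#' @param y per-trial integer labels (>= 2 distinct values)
#' @param cost SVM cost parameter C (> 0)
#' @param scheme multi-class scheme, `"ovo"` or `"ovr"`
#' @param seed seed for the solver's coordinate order (results are
#'   deterministic given data, spec and seed)
#' @return a `micsp_svm` model with a [predict][predict.micsp_svm] method and
#'   a `train_accuracy` element (%).
#' @export
train_svm <- function(x, y, cost = 1, scheme = c("ovo", "ovr"), seed = 1) {
  scheme <- match.arg(scheme)
  if (cost <= 0) stop("cost must be > 0")
  x <- as.matrix(x); y <- as.integer(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data contains a single class")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- cbind(sweep(sweep(x, 2L, mu), 2L, sdv, `/`), 1)
  if (scheme == "ovo") {
    pairs <- utils::combn(classes, 2L)
    Ws <- apply(pairs, 2L, function(pr) {
      sel <- y %in% pr
      yy <- ifelse(y[sel] == pr[1L], 1, -1)
      svm_dcd_train(xs[sel, , drop = FALSE], yy, cost, seed = seed)
    })
    model <- structure(list(scheme = "ovo", classes = classes, pairs = pairs,
                            Ws = Ws, mu = mu, sd = sdv, cost = cost),
                       class = "micsp_svm")
  } else {
    Ws <- vapply(classes, function(cl) {
      yy <- ifelse(y == cl, 1, -1)
      svm_dcd_train(xs, yy, cost, seed = seed)
    }, numeric(ncol(xs)))
    model <- structure(list(scheme = "ovr", classes = classes, Ws = Ws,
                            mu = mu, sd = sdv, cost = cost),
                       class = "micsp_svm")
  }
  model$train_accuracy <- 100 * mean(predict(model, x) == y)
  model
}

#' Predict class labels from a linear SVM
#' @param object a `micsp_svm` model
#' @param newdata trials x features matrix
#' @param ... unused
#' @return integer vector of predicted labels.
#' @export
predict.micsp_svm <- function(object, newdata, ...) {
  xs <- cbind(sweep(sweep(as.matrix(newdata), 2L, object$mu), 2L,
                    object$sd, `/`), 1)
  if (object$scheme == "ovo") {
    votes <- matrix(0L, nrow(xs), length(object$classes))
    for (j in seq_len(ncol(object$pairs))) {
      dec <- xs %*% object$Ws[, j]
      a <- match(object$pairs[1L, j], object$classes)
      b <- match(object$pairs[2L, j], object$classes)
      win <- ifelse(dec > 0, a, b)
      votes[cbind(seq_len(nrow(xs)), win)] <-
        votes[cbind(seq_len(nrow(xs)), win)] + 1L
    }
    # ties broken towards the smallest class label (deterministic)
    object$classes[apply(votes, 1L, which.max)]
  } else {
    dec <- xs %*% object$Ws
    object$classes[apply(dec, 1L, which.max)]
  }
}

## ---- cached covariance machinery for fast cross-validation -------------
# Variances of linearly filtered signals are quadratic forms in per-trial
# cross-product matrices, so covariance estimation, penalty assembly and
# feature extraction inside CV folds all reuse one pass over the raw data.

cv_trial_cache <- function(e) {
  N <- n_channels(e); S <- n_samples(e); Tn <- n_trials(e)
  CnM <- matrix(0, N * N, Tn)   # trace-normalized uncentered cross-products
  CcM <- matrix(0, N * N, Tn)   # centered cross-products (for variances)
  for (i in seq_len(Tn)) {
    x <- trial_matrix(e, i)
    cc <- tcrossprod(x)
    tr <- sum(diag(cc))
    if (tr == 0) stop("zero-energy trial ", i)
    mu <- rowMeans(x)
    CnM[, i] <- cc / tr
    CcM[, i] <- cc - S * tcrossprod(mu)
  }
  list(CnM = CnM, CcM = CcM, N = N, S = S, labels = e$labels)
}

cov_set_from_cache <- function(cache, idx, classes, shrinkage = 1e-6,
                               keep_trials = FALSE) {
  N <- cache$N
  lab <- cache$labels[idx]
  sig <- list(); raw <- list(); tcs <- if (keep_trials) list() else NULL
  for (j in seq_along(classes)) {
    cols <- idx[lab == classes[j]]
    if (!length(cols)) stop("no trials for class ", classes[j], " in this fold")
    m <- matrix(rowMeans(cache$CnM[, cols, drop = FALSE]), N, N)
    m <- sym(m)
    raw[[j]] <- m
    sig[[j]] <- (1 - shrinkage) * m + shrinkage * (sum(diag(m)) / N) * diag(N)
    if (keep_trials)
      tcs[[j]] <- lapply(cols, function(cc) matrix(cache$CnM[, cc], N, N))
  }
  cs <- covariance_set(sig, trial_covs = tcs, classes = classes)
  cs$sigmas_raw <- raw
  cs
}

features_from_cache <- function(cache, W_all, idx) {
  out <- matrix(NA_real_, length(idx), nrow(W_all))
  for (r in seq_along(idx)) {
    cc <- matrix(cache$CcM[, idx[r]], cache$N, cache$N)
    v <- rowSums((W_all %*% cc) * W_all) / (cache$S - 1L)
    out[r, ] <- log(pmax(v, 1e-300))
  }
  out
}

fit_bank <- function(method, cs, alpha = 0, beta = 0, penalties = NULL) {
  switch(method,
         multi_csp = multi_csp(cs),
         gecsp = gecsp(cs),
         strcsp = strcsp(cs, alpha, beta, penalties = penalties),
         stop("unknown method: ", method))
}

w_top_k <- function(fb, k, filter_ends = "both") {
  do.call(rbind, lapply(fb$W, function(w) {
    n <- nrow(w)
    idx <- if (filter_ends == "top") seq_len(k) else {
      # alternate extremes: 1, n, 2, n-1, ...
      ends <- as.vector(rbind(seq_len(ceiling(k / 2)),
                              n + 1L - seq_len(ceiling(k / 2))))
      unique(ends)[seq_len(k)]
    }
    w[idx, , drop = FALSE]
  }))
}

# evaluate every (config, k) candidate by CV over the trials in `idx`
select_by_cv <- function(cache, idx, classes, method, k_grid, configs,
                         n_folds, seed, cost, shrinkage,
                         filter_ends = "both") {
  lab <- cache$labels[idx]
  folds <- make_folds(lab, n_folds, seed)
  acc <- matrix(0, nrow(configs), length(k_grid))
  ntest <- 0L
  for (f in seq_len(n_folds)) {
    tr <- idx[folds != f]; te <- idx[folds == f]
    ntest <- ntest + length(te)
    cs <- cov_set_from_cache(cache, tr, classes, shrinkage,
                             keep_trials = method == "strcsp" &&
                               any(configs$alpha > 0))
    pen <- NULL
    if (method == "strcsp" && any(configs$alpha > 0))
      pen <- lapply(classes, function(cl) stationarity_penalty(cs, cl))
    for (ci in seq_len(nrow(configs))) {
      fb <- fit_bank(method, cs, configs$alpha[ci], configs$beta[ci], pen)
      for (ki in seq_along(k_grid)) {
        W_all <- w_top_k(fb, k_grid[ki], filter_ends)
        m <- train_svm(features_from_cache(cache, W_all, tr),
                       cache$labels[tr], cost, seed = seed)
        pr <- predict(m, features_from_cache(cache, W_all, te))
        acc[ci, ki] <- acc[ci, ki] + sum(pr == cache$labels[te])
      }
    }
  }
  acc <- acc / ntest
  # ties -> smallest alpha+beta (rows pre-sorted), then smallest k
  tacc <- t(acc)
  best <- which(tacc == max(tacc), arr.ind = TRUE)[1L, ]
  list(config = configs[best[2L], , drop = FALSE], k = k_grid[best[1L]],
       cv_accuracy = 100 * max(acc))
}

#' Cross-validated evaluation of a multi-class CSP pipeline
#'
#' Stratified tenfold cross-validation: in each outer fold the spatial
#' filters are fitted on the training trials only, the filter count `k` (and
#' for `strcsp` the regularization weights `alpha`, `beta`) are selected by
#' an inner cross-validation nested inside the training fold, a linear SVM
#' is trained on the training-fold features and scored on the held-out
#' trials. Ties are broken towards the smallest `alpha + beta`, then the
#' smallest `k`.
#'
#' @param e an [epochs] object, already preprocessed (band-passed, cropped)
#' @param method `"multi_csp"`, `"gecsp"` or `"strcsp"`
#' @param k_grid candidate filter counts per class bank
#' @param alpha_grid,beta_grid candidate regularization weights for
#'   `strcsp`; the conventional grid is `c(0, 2^(-8:0))`
#' @param n_folds outer folds (default tenfold)
#' @param n_inner inner folds for the nested selection (default `n_folds`)
#' @param seed integer seed controlling fold assignment and the SVM solver
#' @param cost SVM cost parameter
#' @param nested if `FALSE`, `k`/(`alpha`, `beta`) are selected once by CV on
#'   the full dataset and reused in every outer fold (the single-level
#'   reading of the protocol); the default nested selection is unbiased
#' @param shrinkage covariance shrinkage, see [class_covariances()]
#' @param filter_ends which spectral ends of each bank supply the `k`
#'   filters, see [log_variance_features()]
#' @return a `cv_result`: list with `fold_accuracy` (%), `mean_accuracy`
#'   (%), per-fold `k`, `alpha`, `beta`, `folds`, `method`, `seed`.
#' @export
cross_validate <- function(e, method = c("multi_csp", "gecsp", "strcsp"),
                           k_grid = 1:6, alpha_grid = c(0, 2^(-8:0)),
                           beta_grid = c(0, 2^(-8:0)), n_folds = 10,
                           n_inner = n_folds, seed = 1, cost = 1,
                           nested = TRUE, shrinkage = 1e-6,
                           filter_ends = c("both", "top")) {
  method <- match.arg(method)
  filter_ends <- match.arg(filter_ends)
  classes <- sort(unique(e$labels))
  k_grid <- sort(unique(k_grid))
  if (method == "strcsp") {
    configs <- expand.grid(alpha = sort(unique(alpha_grid)),
                           beta = sort(unique(beta_grid)))
    configs <- configs[order(configs$alpha + configs$beta, configs$alpha), ]
  } else {
    configs <- data.frame(alpha = 0, beta = 0)
  }
  cache <- cv_trial_cache(e)
  all_idx <- seq_len(n_trials(e))
  folds <- make_folds(e$labels, n_folds, seed)
  need_sel <- nrow(configs) > 1L || length(k_grid) > 1L

  fixed_sel <- NULL
  if (!nested && need_sel)
    fixed_sel <- select_by_cv(cache, all_idx, classes, method, k_grid,
                              configs, n_inner, seed + 104729L, cost,
                              shrinkage, filter_ends)

  fold_acc <- numeric(n_folds)
  sel_k <- integer(n_folds); sel_a <- numeric(n_folds); sel_b <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- all_idx[folds != f]; te <- all_idx[folds == f]
    sel <- if (!need_sel) {
      list(config = configs[1L, , drop = FALSE], k = k_grid[1L])
    } else if (nested) {
      select_by_cv(cache, tr, classes, method, k_grid, configs, n_inner,
                   seed + 7919L * f, cost, shrinkage, filter_ends)
    } else fixed_sel
    cs <- cov_set_from_cache(cache, tr, classes, shrinkage,
                             keep_trials = method == "strcsp" &&
                               sel$config$alpha > 0)
    fb <- fit_bank(method, cs, sel$config$alpha, sel$config$beta)
    W_all <- w_top_k(fb, sel$k, filter_ends)
    m <- train_svm(features_from_cache(cache, W_all, tr), cache$labels[tr],
                   cost, seed = seed)
    pr <- predict(m, features_from_cache(cache, W_all, te))
    fold_acc[f] <- 100 * mean(pr == cache$labels[te])
    sel_k[f] <- sel$k
    sel_a[f] <- sel$config$alpha; sel_b[f] <- sel$config$beta
  }
  structure(list(fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
                 k = sel_k, alpha = sel_a, beta = sel_b, folds = folds,
                 method = method, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: mean accuracy %.2f%% over %d folds\n",
              x$method, x$mean_accuracy, length(x$fold_accuracy)))
  cat("fold accuracies (%):", paste(sprintf("%.2f", x$fold_accuracy),
                                    collapse = " "), "\n")
  cat("selected k:", paste(x$k, collapse = " "), "\n")
  if (x$method == "strcsp") {
    cat("selected alpha:", paste(format(x$alpha), collapse = " "), "\n")
    cat("selected beta:", paste(format(x$beta), collapse = " "), "\n")
  }
  invisible(x)
}

#' Compare CSP methods across datasets
#'
#' Runs [cross_validate()] for every method on every dataset (subject) with a
#' common fold assignment per dataset, and compares methods pairwise with a
#' paired t-test over datasets, mirroring the conventional methods x
#' subjects accuracy table.
#'
#' @param epochs_list list of [epochs] objects (one per subject/dataset)
#' @param methods subset of `c("multi_csp", "gecsp", "strcsp")`
#' @param seed integer seed
#' @param ... forwarded to [cross_validate()]
#' @return list with `table` (data.frame: method, one column per dataset,
#'   `mean`) and `tests` (data.frame of pairwise paired t-tests).
#' @export
compare_methods <- function(epochs_list,
                            methods = c("multi_csp", "gecsp", "strcsp"),
                            seed = 1, ...) {
  if (length(methods) < 2L) stop("need >= 2 methods to compare")
  ds <- names(epochs_list)
  if (is.null(ds)) ds <- paste0("S", seq_along(epochs_list))
  acc <- matrix(NA_real_, length(methods), length(epochs_list),
                dimnames = list(methods, ds))
  for (mi in seq_along(methods))
    for (di in seq_along(epochs_list))
      acc[mi, di] <- cross_validate(epochs_list[[di]], methods[mi],
                                    seed = seed, ...)$mean_accuracy
  tab <- data.frame(method = methods, round(acc, 2),
                    mean = round(rowMeans(acc), 2), check.names = FALSE)
  tests <- NULL
  if (length(epochs_list) >= 2L) {
    pr <- utils::combn(methods, 2L)
    tests <- do.call(rbind, lapply(seq_len(ncol(pr)), function(j) {
      a <- acc[pr[1L, j], ]; b <- acc[pr[2L, j], ]
      d <- a - b
      if (stats::sd(d) == 0) {
        data.frame(method_a = pr[1L, j], method_b = pr[2L, j],
                   t = 0, p = 1)
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        data.frame(method_a = pr[1L, j], method_b = pr[2L, j],
                   t = unname(tt$statistic), p = tt$p.value)
      }
    }))
  } else warning("single dataset: paired t-test skipped")
  list(table = tab, tests = tests, accuracies = acc)
}
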