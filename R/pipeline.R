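# Reproducible end-to-end workflows: the feature-comparison report (ERSP
# power curves, PSE, SDC, topographies over the six simple-vs-compound
# comparison groups) and the classification benchmark (methods x subjects
# accuracy table). All outputs are plain CSV/JSON plus a manifest naming the
# configuration and seed that reproduce them.

#' The six simple-vs-compound comparison groups
#'
#' Pairs of class labels (compound, simple): BH vs LH, BH vs RH, LH&RF vs LH,
#' RH&LF vs RH, LH&RF vs F, RH&LF vs F.
#' @return list of length-2 integer vectors `c(compound, simple)`.
#' @export
comparison_groups <- function() {
  list(c(4L, 1L), c(4L, 2L), c(5L, 1L), c(6L, 2L), c(5L, 3L), c(6L, 3L))
}

group_tag <- function(g) {
  nm <- gsub("&", "", class_names())
  paste0(nm[g[1L]], "_vs_", nm[g[2L]])
}

# paired t robust to zero-variance differences (identical conditions)
safe_paired_t <- function(a, b) {
  d <- a - b
  if (stats::sd(d) == 0) return(list(t = 0, p = 1))
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

write_manifest <- function(out_dir, what, cfg) {
  man <- list(what = what, package = "micsp",
              version = as.character(utils::packageVersion("micsp")),
              r_version = R.version.string,
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = cfg)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Feature-comparison report
#'
#' For a cohort of subjects: per-group/per-electrode power-curve comparisons
#' with per-frequency paired t-tests, per-electrode PSE tables with paired
#' group tests, SDC tables with paired group tests, and per-class scalp
#' topography tables. Epochs are expected raw (uncropped, unfiltered);
#' the spectral analyses use them as given.
#'
#' @param epochs_list list of [epochs] objects, one per subject; every
#'   subject must contain all classes referenced by the groups
#' @param out_dir output directory (created if missing)
#' @param groups comparison groups, as [comparison_groups()]
#' @param electrodes electrodes for ERSP/PSE curves (default C3, Cz, C4)
#' @param imagery imagery window in seconds for curve averaging
#' @param pse_band PSE analysis band in Hz
#' @param alpha_band band for SDC/topography in Hz
#' @param alpha significance level
#' @param topo_maps also write per-class topography tables (uses the first
#'   subject; averaged topographies get expensive for large cohorts)
#' @return invisibly, a list with the in-memory tables that were written.
#' @export
run_feature_comparison <- function(epochs_list, out_dir,
                                   groups = comparison_groups(),
                                   electrodes = c("C3", "CZ", "C4"),
                                   imagery = c(3, 7), pse_band = c(5, 35),
                                   alpha_band = c(8, 13), alpha = 0.05,
                                   topo_maps = FALSE) {
  if (length(epochs_list) < 2L)
    stop("group statistics need >= 2 subjects")
  need <- sort(unique(c(unlist(groups), 7L)))
  for (si in seq_along(epochs_list)) {
    have <- unique(epochs_list[[si]]$labels)
    if (length(setdiff(need, have)))
      stop("subject ", si, " lacks class(es): ",
           paste(setdiff(need, have), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ns <- length(epochs_list)
  res <- list()

  # ERSP power-change curves per subject x class x electrode
  classes <- sort(unique(unlist(groups)))
  curves <- list()  # [[electrode]][[class]] = subjects x freq
  for (ch in electrodes) {
    curves[[ch]] <- list()
    for (cl in classes) {
      maps <- lapply(epochs_list, function(e) ersp(e, cl, ch))
      curves[[ch]][[as.character(cl)]] <-
        band_power_curve(maps, imagery = imagery)
    }
  }
  freqs <- curves[[1L]][[1L]]$freqs
  for (g in groups) for (ch in electrodes) {
    a <- curves[[ch]][[as.character(g[1L])]]
    b <- curves[[ch]][[as.character(g[2L])]]
    tt <- paired_freq_ttest(a$per_subject, b$per_subject, alpha, freqs)
    tab <- data.frame(freq = freqs, compound = a$values, simple = b$values,
                      t = tt$t, p = tt$p, sig = tt$sig)
    fn <- file.path(out_dir, paste0("group_", group_tag(g), "_", ch, ".csv"))
    utils::write.csv(tab, fn, row.names = FALSE)
    res$groups[[paste(group_tag(g), ch, sep = "_")]] <- tab
  }

  # PSE per subject x class x electrode, with per-group paired tests
  pse_rows <- list(); pse_tests <- list()
  pse_vals <- array(NA_real_, c(ns, length(classes), length(electrodes)),
                    dimnames = list(NULL, as.character(classes), electrodes))
  for (si in seq_len(ns)) for (ch in electrodes) {
    v <- pse_per_class(epochs_list[[si]], ch, band = pse_band,
                       classes = classes, interval = imagery)
    pse_vals[si, , ch] <- v
    pse_rows[[length(pse_rows) + 1L]] <-
      data.frame(subject = si, electrode = ch, class = classes,
                 task = class_names()[classes], pse = unname(v))
  }
  utils::write.csv(do.call(rbind, pse_rows),
                   file.path(out_dir, "pse_values.csv"), row.names = FALSE)
  for (g in groups) for (ch in electrodes) {
    a <- pse_vals[, as.character(g[1L]), ch]
    b <- pse_vals[, as.character(g[2L]), ch]
    tt <- safe_paired_t(a, b)
    pse_tests[[length(pse_tests) + 1L]] <-
      data.frame(group = group_tag(g), electrode = ch,
                 mean_compound = mean(a), mean_simple = mean(b),
                 t = tt$t, p = tt$p, sig = tt$p < alpha)
  }
  res$pse_tests <- do.call(rbind, pse_tests)
  utils::write.csv(res$pse_tests, file.path(out_dir, "pse_tests.csv"),
                   row.names = FALSE)

  # SDC per subject x class (task vs rest alpha-band PSD over scalp channels)
  scalp <- setdiff(epochs_list[[1L]]$channels, excluded_channels())
  sdc_vals <- matrix(NA_real_, ns, length(classes),
                     dimnames = list(NULL, as.character(classes)))
  for (si in seq_len(ns)) {
    e <- epochs_list[[si]]
    rest <- band_psd_per_channel(e, 7L, band = alpha_band,
                                 interval = imagery, electrodes = scalp)
    for (cl in classes) {
      task <- band_psd_per_channel(e, cl, band = alpha_band,
                                   interval = imagery, electrodes = scalp)
      sdc_vals[si, as.character(cl)] <- sdc(task, rest)
    }
  }
  utils::write.csv(data.frame(subject = seq_len(ns), sdc_vals,
                              check.names = FALSE),
                   file.path(out_dir, "sdc_values.csv"), row.names = FALSE)
  sdc_tests <- do.call(rbind, lapply(groups, function(g) {
    a <- sdc_vals[, as.character(g[1L])]
    b <- sdc_vals[, as.character(g[2L])]
    tt <- safe_paired_t(a, b)
    data.frame(group = group_tag(g), mean_compound = mean(a),
               mean_simple = mean(b), t = tt$t, p = tt$p,
               sig = tt$p < alpha)
  }))
  res$sdc_tests <- sdc_tests
  utils::write.csv(sdc_tests, file.path(out_dir, "sdc_tests.csv"),
                   row.names = FALSE)

  if (topo_maps) {
    for (cl in classes) {
      tp <- topography(epochs_list[[1L]], cl, band = alpha_band,
                       interval = imagery)
      utils::write.csv(data.frame(electrode = names(tp), ersp_db = unname(tp)),
                       file.path(out_dir, paste0("topography_",
                                                 gsub("&", "", class_names()[cl]),
                                                 ".csv")),
                       row.names = FALSE)
    }
  }

  write_manifest(out_dir, "feature_comparison",
                 list(n_subjects = ns, electrodes = electrodes,
                      imagery = imagery, pse_band = pse_band,
                      alpha_band = alpha_band, alpha = alpha,
                      groups = vapply(groups, group_tag, character(1L))))
  invisible(res)
}

#' Classification benchmark
#'
#' Preprocesses each subject's epochs for classification (CAR, 8-30 Hz,
#' imagery-window crop), runs cross-validated evaluation for every method
#' and writes the methods x subjects accuracy table with pairwise paired
#' t-tests, as CSV and JSON.
#'
#' @param epochs_list list of [epochs] objects (one per subject), raw
#' @param out_dir output directory
#' @param methods subset of `c("multi_csp", "gecsp", "strcsp")`
#' @param band,interval,target_fs preprocessing for classification
#' @param seed integer seed
#' @param ... forwarded to [cross_validate()] (grids, folds, cost, ...)
#' @return invisibly, the [compare_methods()] result.
#' @export
run_classification_benchmark <- function(epochs_list, out_dir,
                                         methods = c("multi_csp", "gecsp",
                                                     "strcsp"),
                                         band = c(8, 30),
                                         interval = c(3.5, 6.5),
                                         target_fs = NULL, seed = 1, ...) {
  bad <- setdiff(methods, c("multi_csp", "gecsp", "strcsp"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- lapply(epochs_list, preprocess, car = TRUE, band = band,
                 target_fs = target_fs, interval = interval)
  if (length(methods) >= 2L) {
    cmp <- compare_methods(prep, methods, seed = seed, ...)
  } else {
    cv <- cross_validate(prep[[1L]], methods, seed = seed, ...)
    acc <- matrix(cv$mean_accuracy, 1L, length(prep),
                  dimnames = list(methods, paste0("S", seq_along(prep))))
    cmp <- list(table = data.frame(method = methods, round(acc, 2),
                                   mean = round(rowMeans(acc), 2),
                                   check.names = FALSE),
                tests = NULL, accuracies = acc)
  }
  utils::write.csv(cmp$table, file.path(out_dir, "accuracy_table.csv"),
                   row.names = FALSE)
  if (!is.null(cmp$tests))
    utils::write.csv(cmp$tests, file.path(out_dir, "method_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(table = cmp$table, tests = cmp$tests),
                       file.path(out_dir, "accuracy_table.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "classification_benchmark",
                 list(n_subjects = length(epochs_list), methods = methods,
                      band = band, interval = interval, seed = seed))
  invisible(cmp)
}
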