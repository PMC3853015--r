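#' Epoched multichannel EEG
#'
#' The universal exchange container of the package: a trial-major tensor of
#' epoched EEG with class labels and channel metadata. Labels code the seven
#' mental tasks: 1 = left hand (LH), 2 = right hand (RH), 3 = feet (F),
#' 4 = both hands (BH), 5 = left hand & right foot (LH&RF),
#' 6 = right hand & left foot (RH&LF), 7 = rest (R).
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param labels integer vector, one label in 1..7 per trial.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel names, one per channel.
#' @param t0 time of the first sample relative to trial start, in seconds.
#'
#' @return An object of class `epochs`: a list with elements `data`, `labels`,
#'   `fs`, `channels`, `t0`.
#' @export
epochs <- function(data, labels, fs, channels, t0 = 0) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x channels x samples)")
  e <- structure(
    list(data = data, labels = as.integer(labels), fs = as.numeric(fs),
         channels = as.character(channels), t0 = as.numeric(t0)),
    class = "epochs")
  validate_epochs(e)
}

validate_epochs <- function(e) {
  d <- dim(e$data)
  if (length(e$labels) != d[1L])
    stop("number of labels (", length(e$labels), ") != number of trials (", d[1L], ")")
  if (any(is.na(e$labels)) || any(e$labels < 1L | e$labels > 7L))
    stop("labels must all lie in {1..7}")
  if (!is.finite(e$fs) || e$fs <= 0) stop("fs must be > 0")
  if (length(e$channels) != d[2L])
    stop("number of channel names (", length(e$channels),
         ") != number of channels (", d[2L], ")")
  if (anyDuplicated(e$channels)) stop("channel names must be unique")
  e
}

n_trials   <- function(e) dim(e$data)[1L]
n_channels <- function(e) dim(e$data)[2L]
n_samples  <- function(e) dim(e$data)[3L]

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs> %d trials x %d channels x %d samples @ %g Hz (t0 = %g s)\n",
              d[1L], d[2L], d[3L], x$fs, x$t0))
  cat("labels:", paste(sprintf("%d:%d", as.integer(names(table(x$labels))),
                               as.integer(table(x$labels))), collapse = " "), "\n")
  invisible(x)
}

#' Extract one trial as a channels x samples matrix
#' @param e an [epochs] object
#' @param i trial index
#' @return numeric matrix, channels x samples.
#' @export
trial_matrix <- function(e, i) {
  m <- e$data[i, , , drop = FALSE]
  dim(m) <- dim(e$data)[2:3]
  m
}

#' Subset epochs by trial
#' @param e an [epochs] object
#' @param idx integer or logical trial index
#' @return an [epochs] object with the selected trials, in the given order.
#' @export
select_trials <- function(e, idx) {
  epochs(e$data[idx, , , drop = FALSE], e$labels[idx], e$fs, e$channels, e$t0)
}

#' Save / load the HDF5 epoch container
#'
#' Fixed dataset layout: `/data` (float64, trials x channels x samples),
#' `/labels` (int), `/fs` (scalar), `/channels` (UTF-8 strings), `/t0`
#' (scalar). `load_epochs()` of a file written by `save_epochs()` reproduces
#' the object bit-identically.
#'
#' @param e an [epochs] object
#' @param path file path (`.h5`); overwritten if present.
#' @return `save_epochs()` returns `path` invisibly; `load_epochs()` an
#'   [epochs] object.
#' @export
save_epochs <- function(e, path) {
  validate_epochs(e)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(e$data, path, "data")
  rhdf5::h5write(e$labels, path, "labels")
  rhdf5::h5write(e$fs, path, "fs")
  rhdf5::h5write(e$channels, path, "channels")
  rhdf5::h5write(e$t0, path, "t0")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  have <- rhdf5::h5ls(path)$name
  need <- c("data", "labels", "fs", "channels", "t0")
  miss <- setdiff(need, have)
  if (length(miss))
    stop("epoch container is missing dataset(s): ", paste(miss, collapse = ", "))
  e <- epochs(rhdf5::h5read(path, "data"),
              as.integer(rhdf5::h5read(path, "labels")),
              as.numeric(rhdf5::h5read(path, "fs")),
              as.character(rhdf5::h5read(path, "channels")),
              as.numeric(rhdf5::h5read(path, "t0")))
  rhdf5::h5closeAll()
  e
}

#' Read a channel layout from a CSV file
#'
#' Expected columns: `name`, `x`, `y` with coordinates inside the unit disc
#' (top view, nose up, x = right, y = anterior).
#'
#' @param path CSV path
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
read_layout <- function(path) {
  lay <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y") %in% names(lay)))
    stop("layout CSV must have columns name, x, y")
  if (anyDuplicated(lay$name)) stop("duplicate channel names in layout")
  r <- sqrt(lay$x^2 + lay$y^2)
  if (any(r > 1 + 1e-9)) stop("layout coordinates must lie within the unit disc")
  lay[, c("name", "x", "y")]
}
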