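#' Default 64-channel 10/20 montage layout
#'
#' A 64-channel extended 10/20 montage of the kind used by 64-electrode
#' Ag/AgCl caps: 60 scalp electrodes plus the two ocular channels (HEO, VEO)
#' and the two cerebellar/inion-line electrodes (CB1, CB2) that are
#' conventionally excluded from scalp topographies. Coordinates are a
#' schematic top view inside the unit disc (nose up, x = right,
#' y = anterior); they are layout positions for topography and for the
#' synthetic generator's spatial mixing, not digitized electrode positions.
#'
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
default_layout <- function() {
  row <- function(names, y, half_width) {
    n <- length(names)
    x <- if (n == 1L) 0 else seq(-half_width, half_width, length.out = n)
    data.frame(name = names, x = x, y = y, stringsAsFactors = FALSE)
  }
  lay <- rbind(
    row(c("FP1", "FPZ", "FP2"), 0.85, 0.30),
    row(c("AF3", "AF4"), 0.70, 0.25),
    row(c("F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8"), 0.55, 0.70),
    row(c("FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8"), 0.28, 0.80),
    row(c("T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8"), 0.00, 0.90),
    row(c("TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8"), -0.28, 0.80),
    row(c("P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8"), -0.55, 0.70),
    row(c("PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8"), -0.70, 0.55),
    row(c("O1", "OZ", "O2"), -0.85, 0.25),
    data.frame(name = c("CB1", "CB2"), x = c(-0.42, 0.42), y = -0.90,
               stringsAsFactors = FALSE),
    data.frame(name = c("HEO", "VEO"), x = c(0.94, 0.10), y = c(0.10, 0.94),
               stringsAsFactors = FALSE)
  )
  rownames(lay) <- NULL
  lay
}

#' Non-scalp channels excluded from topographies
#'
#' The ocular (HEO, VEO) and cerebellar (CB1, CB2) electrodes, excluded when
#' averaging scalp maps over the remaining 60 electrodes.
#' @return character vector of channel names.
#' @export
excluded_channels <- function() c("HEO", "VEO", "CB1", "CB2")
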