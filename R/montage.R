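#' Standard 37-channel fronto-central/parietal 10-10 montage
#'
#' The electrode subset covering prefrontal to parietal midline rows
#' (AF3-4; Fz, F1-F6; FCz, FC1-FC6; Cz, C1-C6; CPz, CP1-CP6; Pz, P1-P6),
#' i.e. the channels over and around the sensorimotor cortex used for
#' ErrP analysis.
#'
#' @return character vector of 37 channel labels.
#' @export
standardMontage <- function() {
  rows <- list(AF = c(3, 4), F = 1:6, FC = 1:6, C = 1:6, CP = 1:6, P = 1:6)
  out <- character()
  for (pre in names(rows)) {
    if (pre != "AF") out <- c(out, paste0(pre, "z"))
    out <- c(out, paste0(pre, rows[[pre]]))
  }
  out
}

# Approximate flat (x, y) scalp coordinates for the supported rows of the
# 10-10 system, on a unit head: y runs anterior (+) to posterior (-),
# x left (-) to right (+). Only used for the simulator's spatial weighting;
# not a geodesic montage.
channelPositions <- function(labels) {
  rowY <- c(AF = 0.75, F = 0.55, FC = 0.28, C = 0, CP = -0.28, P = -0.55)
  pos <- matrix(NA_real_, nrow = length(labels), ncol = 2L,
                dimnames = list(labels, c("x", "y")))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1L]]
    if (length(m) != 3L || !m[2L] %in% names(rowY))
      stopInvalid("unsupported channel label '%s'", lab)
    y <- rowY[[m[2L]]]
    if (m[3L] == "z") {
      x <- 0
    } else {
      k <- as.integer(m[3L])
      # odd numbers left hemisphere, even right; spacing 0.2 per step
      x <- ceiling(k / 2) * 0.2 * if (k %% 2L == 1L) -1 else 1
    }
    pos[i, ] <- c(x, y)
  }
  pos
}

# Gaussian spatial weighting of the feedback-locked potential, peaking
# between FCz and Cz (fronto-central maximum typical of the ErrP) and
# decaying with scalp distance.
spatialWeights <- function(labels, center = c(0, 0.14), sigma = 0.45) {
  pos <- channelPositions(labels)
  d2 <- (pos[, 1L] - center[1L])^2 + (pos[, 2L] - center[2L])^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- labels
  w
}
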