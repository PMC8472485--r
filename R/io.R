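# --- EDF (European Data Format) continuous-recording writer/reader ----
# Minimal EDF support: one physical dimension (uV), 1-second data
# records, 16-bit samples. The last record is zero-padded; the true
# sample count is stored in the header's reserved field so the reader
# can trim the padding.

edfPad <- function(x, n) {
  s <- as.character(x)
  if (any(nchar(s) > n)) stopInvalid("EDF header field overflow")
  formatC(s, width = n, flag = "-")
}

# format a physical-range value into EDF's fixed 8-character field
edfNum <- function(x) {
  vapply(x, function(v) {
    for (fmt in c("%.6g", "%.4g", "%.2g", "%.1e")) {
      s <- sprintf(fmt, v)
      if (nchar(s) <= 8L) return(s)
    }
    stopInvalid("cannot format %g into an 8-character EDF field", v)
  }, "")
}

#' Write a Recording to an EDF file (plus a CSV event file)
#'
#' Signals are stored as 16-bit integers with per-channel physical
#' ranges; quantization error is bounded by range/65536 per channel.
#' Events (sample index, time and code) go to a companion CSV since
#' plain EDF has no annotation channel.
#'
#' @param recording a [Recording-class].
#' @param path output EDF path.
#' @param eventsPath output CSV path (default: `path` with `.events.csv`).
#' @return invisibly, the EDF path.
#' @export
writeRecordingEdf <- function(recording, path,
                              eventsPath = sub("\\.edf$", ".events.csv",
                                               path)) {
  stopifnot(is(recording, "Recording"))
  sig <- recording@signal
  fs <- recording@fs
  nCh <- nrow(sig)
  nSamp <- ncol(sig)
  sampPerRec <- as.integer(round(fs))          # 1-second records
  nRec <- as.integer(ceiling(nSamp / sampPerRec))
  physMin <- apply(sig, 1L, min); physMax <- apply(sig, 1L, max)
  flat <- physMax - physMin < 1e-9
  physMax[flat] <- physMin[flat] + 1           # avoid zero range
  # round ranges to their 8-character header representation so writer and
  # reader use identical scale factors
  physMin <- as.numeric(edfNum(physMin - abs(physMin) * 1e-6))
  physMax <- as.numeric(edfNum(physMax + abs(physMax) * 1e-6))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8L), edfPad("X X X X", 80L),
    edfPad(sprintf("Startdate X nsamples=%d", nSamp), 80L),
    edfPad("01.01.26", 8L), edfPad("00.00.00", 8L),
    edfPad(256L + 256L * nCh, 8L), edfPad("", 44L),
    edfPad(nRec, 8L), edfPad("1", 8L), edfPad(nCh, 4L))
  field <- function(vals, w) paste(vapply(vals, edfPad, "", n = w),
                                   collapse = "")
  hdr <- paste0(hdr,
    field(recording@channels, 16L), field(rep("", nCh), 80L),
    field(rep("uV", nCh), 8L),
    field(edfNum(physMin), 8L), field(edfNum(physMax), 8L),
    field(rep(-32768L, nCh), 8L), field(rep(32767L, nCh), 8L),
    field(rep("", nCh), 80L), field(rep(sampPerRec, nCh), 8L),
    field(rep("", nCh), 32L))
  writeChar(hdr, con, eos = NULL)
  scale <- 65535 / (physMax - physMin)
  padded <- matrix(0, nCh, nRec * sampPerRec)
  padded[, seq_len(nSamp)] <- sig
  for (r in seq_len(nRec)) {
    idx <- (r - 1L) * sampPerRec + seq_len(sampPerRec)
    for (c_ in seq_len(nCh)) {
      dig <- as.integer(round((padded[c_, idx] - physMin[c_]) * scale[c_]) -
                          32768)
      writeBin(pmin(pmax(dig, -32768L), 32767L), con, size = 2L,
               endian = "little")
    }
  }
  ev <- recording@events
  utils::write.csv(data.frame(sample_index = ev$sample,
                              time_s = (ev$sample - 1L) / fs,
                              code = ev$code),
                   eventsPath, row.names = FALSE)
  invisible(path)
}

#' Read a Recording from an EDF file written by [writeRecordingEdf()]
#'
#' @param path EDF path.
#' @param eventsPath companion event CSV (default derived from `path`);
#'   if missing, the recording has no events.
#' @param participant,day identifiers for the returned object.
#' @return a [Recording-class].
#' @export
readRecordingEdf <- function(path, eventsPath = sub("\\.edf$",
                                                    ".events.csv", path),
                             participant = "p1", day = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8L); rd(80L)
  recField <- rd(80L)
  rd(8L); rd(8L); rd(8L); rd(44L)
  nRec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  nCh <- as.integer(rd(4L))
  labels <- vapply(seq_len(nCh), function(i) rd(16L), "")
  for (i in seq_len(nCh)) rd(80L)              # transducer
  for (i in seq_len(nCh)) rd(8L)               # dimension
  physMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8L), ""))
  physMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8L), ""))
  digMin <- as.numeric(vapply(seq_len(nCh), function(i) rd(8L), ""))
  digMax <- as.numeric(vapply(seq_len(nCh), function(i) rd(8L), ""))
  for (i in seq_len(nCh)) rd(80L)              # prefilter
  sampPerRec <- as.integer(vapply(seq_len(nCh), function(i) rd(8L), ""))
  for (i in seq_len(nCh)) rd(32L)
  fs <- sampPerRec[1L] / recDur
  sig <- matrix(0, nCh, nRec * sampPerRec[1L])
  for (r in seq_len(nRec)) {
    for (c_ in seq_len(nCh)) {
      dig <- readBin(con, "integer", n = sampPerRec[c_], size = 2L,
                     signed = TRUE, endian = "little")
      idx <- (r - 1L) * sampPerRec[c_] + seq_len(sampPerRec[c_])
      sig[c_, idx] <- physMin[c_] + (dig - digMin[c_]) *
        (physMax[c_] - physMin[c_]) / (digMax[c_] - digMin[c_])
    }
  }
  m <- regmatches(recField, regexec("nsamples=([0-9]+)", recField))[[1L]]
  if (length(m) == 2L) sig <- sig[, seq_len(as.integer(m[2L])), drop = FALSE]
  events <- if (file.exists(eventsPath)) {
    ev <- utils::read.csv(eventsPath, stringsAsFactors = FALSE)
    data.frame(sample = ev$sample_index, code = ev$code,
               stringsAsFactors = FALSE)
  } else data.frame(sample = integer(), code = character())
  new("Recording", signal = sig, channels = labels, fs = fs,
      events = events, participant = as.character(participant),
      day = as.integer(day))
}

# --- EpochSet container: flat CSV + JSON sidecar ----------------------

#' Write an EpochSet to a flat CSV plus JSON sidecar
#'
#' The CSV holds one row per epoch (channel-major flattening of the
#' channels x samples tensor); the sidecar records labels, window,
#' sampling rate, channel list and provenance, so the pair round-trips
#' losslessly (up to text precision).
#'
#' @param epochs an [EpochSet-class].
#' @param path CSV path; the sidecar is `path` + `.json`.
#' @return invisibly, `path`.
#' @export
writeEpochSet <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  d <- dim(epochs@data)
  X <- t(vapply(seq_len(d[3L]),
                function(i) as.numeric(t(epochs@data[, , i])),
                numeric(d[1L] * d[2L])))
  utils::write.csv(X, path, row.names = FALSE)
  side <- list(labels = as.character(epochs@labels),
               window_ms = epochs@window, fs_hz = epochs@fs,
               channels = epochs@channels,
               provenance = epochs@provenance,
               dim = d)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an EpochSet written by [writeEpochSet()]
#'
#' @param path CSV path (sidecar expected at `path` + `.json`).
#' @return an [EpochSet-class].
#' @export
readEpochSet <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(utils::read.csv(path))
  d <- as.integer(side$dim)
  dat <- array(0, dim = d)
  for (i in seq_len(d[3L]))
    dat[, , i] <- matrix(X[i, ], nrow = d[1L], ncol = d[2L], byrow = TRUE)
  new("EpochSet", data = dat, labels = errpFactor(side$labels),
      window = as.numeric(side$window_ms), fs = side$fs_hz,
      channels = side$channels,
      provenance = as.data.frame(side$provenance))
}

#' Write a FeatureMatrix to CSV
#'
#' One row per trial; the header encodes each column's (channel,
#' latency) provenance; a `label` column holds the class.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
writeFeatureMatrixCsv <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  df <- as.data.frame(fm@X)
  df$label <- as.character(fm@labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- experiment configuration -----------------------------------------

#' Default experiment configuration
#'
#' The full configuration of a simulated two-day cohort experiment with
#' the standard acquisition and preprocessing settings: 1200 Hz,
#' 37-channel montage, 400 trials per session at a 70/30 correct/error
#' ratio, 0.05-10 Hz order-8 zero-phase band-pass, [100, 500) ms epochs,
#' 150 uV rejection, balancing, and the three calibration schemes for
#' the three method arms.
#'
#' @param masterSeed integer master seed; all stage seeds derive from it.
#' @return nested named list; see [runExperiment()].
#' @export
defaultExperimentConfig <- function(masterSeed = 1L) {
  list(
    cohort = list(nParticipants = 25L, nDays = 2L, fs = 1200,
                  nPerMovement = 100L, ratioCorrect = 0.7,
                  montage = standardMontage(),
                  phases = c(idle = 5, preparation = 3,
                             feedback_delay = 3, post = 1)),
    template = erpTemplateParams(),
    profile = variabilityProfile(),
    preprocess = preprocessConfig(),
    methods = c("mlp-features", "mlp-epoch", "slda-features"),
    schemes = c("within-day", "between-day", "across-participant"),
    cvFolds = 10L,
    masterSeed = as.integer(masterSeed))
}

#' Read an experiment configuration from YAML or JSON
#'
#' Unspecified settings fall back to [defaultExperimentConfig()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return configuration list.
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stopInvalid("config file '%s' does not exist", path)
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- defaultExperimentConfig()
  mergeList <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        mergeList(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- mergeList(cfg, raw)
  if (!is.null(raw$cohort$phases))
    cfg$cohort$phases <- unlist(raw$cohort$phases)
  cfg$masterSeed <- as.integer(cfg$masterSeed)
  cfg
}

#' Write a cohort manifest as JSON
#'
#' Records ids, dimensions and file paths of a simulated cohort so a run
#' can be reproduced or reloaded.
#'
#' @param recordings list of [Recording-class] (as from [makeCohort()]).
#' @param paths character vector of EDF paths, parallel to `recordings`.
#' @param path manifest output path.
#' @return invisibly, `path`.
#' @export
writeCohortManifest <- function(recordings, paths, path) {
  entries <- lapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    list(participant = r@participant, day = r@day, file = paths[i],
         fs_hz = r@fs, n_channels = length(r@channels),
         n_samples = ncol(r@signal), n_events = nrow(r@events))
  })
  jsonlite::write_json(list(recordings = entries), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
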