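#' Run a full simulated decoding experiment
#'
#' End-to-end orchestration: synthesize the cohort, preprocess every
#' session (filter, bad channels, epoching, rejection, normalization,
#' balancing), then evaluate every requested calibration scheme for
#' every method arm. All randomness derives from the master seed via
#' stage-tagged seeds, so two runs of the same configuration produce
#' identical results.
#'
#' @param config configuration list as from [defaultExperimentConfig()]
#'   or [readExperimentConfig()].
#' @param outDir optional directory; when given, `results.csv`,
#'   `exclusions.csv` and `manifest.json` are written there.
#' @return list with `results` (tidy data.frame: participant, day,
#'   scheme, method, unit, n_test, accuracy, chance_level, seed),
#'   `exclusions` (per-session bad-channel and rejected-epoch counts)
#'   and `manifest` (run metadata).
#' @export
runExperiment <- function(config = defaultExperimentConfig(),
                          outDir = NULL) {
  co <- config$cohort
  seed <- config$masterSeed
  recs <- makeCohort(nParticipants = co$nParticipants, nDays = co$nDays,
                     profile = config$profile, template = config$template,
                     montage = co$montage, fs = co$fs,
                     nPerMovement = co$nPerMovement,
                     ratioCorrect = co$ratioCorrect, phases = co$phases,
                     seed = deriveSeed(seed, "cohort"))
  nP <- co$nParticipants; nD <- co$nDays
  epochs <- vector("list", length(recs))
  excl <- data.frame()
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    e <- preprocessRecording(r, config$preprocess,
                             seed = deriveSeed(seed, paste0("balance/",
                                                            names(recs)[i])))
    ex <- attr(e, "exclusions")
    excl <- rbind(excl, data.frame(
      participant = r@participant, day = r@day,
      n_trials = sum(grepl("^feedback", r@events$code)),
      bad_channels = length(ex$badChannels),
      rejected_epochs = ex$nRejected,
      epochs_retained = nTrials(e)))
    epochs[[i]] <- e
  }
  names(epochs) <- names(recs)
  byPD <- function(p, d) epochs[[sprintf("p%d_d%d", p, d)]]

  rows <- list()
  addRows <- function(res, participant, day) {
    u <- names(accuracies(res))
    rows[[length(rows) + 1L]] <<- data.frame(
      participant = participant, day = day, scheme = res@scheme,
      method = res@method, unit = u, n_test = unname(res@nTest),
      accuracy = unname(accuracies(res)),
      chance_level = unname(chanceLevels(res)), seed = seed)
  }
  for (method in config$methods) {
    spec <- classifierSpec(method,
                           seed = deriveSeed(seed, paste0("mlp/", method)))
    if ("within-day" %in% config$schemes) {
      for (p in seq_len(nP)) for (d in seq_len(nD)) {
        res <- withinDayCV(byPD(p, d), spec, k = config$cvFolds,
                           seed = deriveSeed(seed,
                                             sprintf("cv/%s/%d/%d",
                                                     method, p, d)))
        addRows(res, sprintf("p%d", p), d)
      }
    }
    if ("between-day" %in% config$schemes && nD >= 2L) {
      for (p in seq_len(nP)) {
        res <- betweenDay(byPD(p, 1L), byPD(p, 2L), spec)
        addRows(res, sprintf("p%d", p), NA_integer_)
      }
    }
    if ("across-participant" %in% config$schemes && nP >= 2L) {
      for (d in seq_len(nD)) {
        sets <- lapply(seq_len(nP), byPD, d = d)
        names(sets) <- sprintf("p%d", seq_len(nP))
        res <- acrossParticipantLopo(sets, spec)
        u <- names(accuracies(res))
        rows[[length(rows) + 1L]] <- data.frame(
          participant = u, day = d, scheme = res@scheme, method = res@method,
          unit = u, n_test = unname(res@nTest),
          accuracy = unname(accuracies(res)),
          chance_level = unname(chanceLevels(res)), seed = seed)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  manifest <- list(masterSeed = seed,
                   nParticipants = nP, nDays = nD,
                   fs_hz = co$fs, nPerMovement = co$nPerMovement,
                   ratioCorrect = co$ratioCorrect,
                   nChannels = length(co$montage),
                   methods = config$methods, schemes = config$schemes,
                   package_version =
                     as.character(utils::packageVersion("ErrPDecode")))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(outDir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(excl, file.path(outDir, "exclusions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, exclusions = excl, manifest = manifest)
}
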