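test_that("chance level matches exhaustive binomial enumeration up to n = 200", {
  # oracle: sum the exact tail by enumeration, take the smallest k
  oracle <- function(n, alpha = 0.05) {
    pmf <- dbinom(0:n, n, 0.5)
    for (k in 0:n) {
      if (sum(pmf[(k + 1):(n + 1)]) <= alpha + 1e-15) return(k / n)
    }
    1.0
  }
  for (n in 1:200) {
    got <- suppressWarnings(chanceLevel(n))
    expect_equal(got, oracle(n), info = sprintf("n = %d", n))
  }
  expect_equal(chanceLevel(20, 2, 0.05), 0.75)
  expect_equal(chanceLevel(5, 2, 0.05), 1.0)
})

test_that("chance level is non-increasing in the test-set size", {
  lv <- suppressWarnings(vapply(1:200, chanceLevel, numeric(1)))
  # monotone along the achievable envelope: compare block minima
  expect_true(all(diff(vapply(seq(10, 200, 10),
                              function(n) min(lv[1:n]), numeric(1))) <= 0))
  expect_lt(lv[200], lv[20])
  expect_warning(chanceLevel(3), "significant")
})

test_that("stratified k-fold CV partitions every trial exactly once", {
  ep <- noiseEpochs(100, nCh = 2, nSamp = 10)
  res <- withinDayCV(ep, classifierSpec("slda-features", targetHz = 50),
                     k = 10, seed = 2)
  expect_length(accuracies(res), 10L)
  expect_equal(unname(chanceLevels(res)), rep(0.9, 10))  # n_test = 10 each
  expect_equal(sum(res@nTest), 100)
  expect_true(all(res@nTest == 10))
  expect_true(all(accuracies(res) >= 0 & accuracies(res) <= 1))
  expect_error(withinDayCV(ep, k = 101), "at least k")
})

test_that("a separable session is decoded nearly perfectly within day", {
  ep <- makeTestEpochs(seed = 3, nPerMovement = 25L,
                       profile = cleanProfile(noiseRms_uV = 0.3))
  res <- withinDayCV(ep, classifierSpec("slda-features"), seed = 1)
  expect_gte(meanAccuracy(res), 0.95)
})

test_that("no-signal sessions stay inside the binomial CI of chance", {
  # pure noise epochs: no class structure at all
  ep <- noiseEpochs(120, nCh = 3, nSamp = 20, seed = 8)
  res <- suppressWarnings(
    withinDayCV(ep, classifierSpec("slda-features"), seed = 4))
  nCorrect <- sum(accuracies(res) * res@nTest)
  ci <- qbinom(c(0.025, 0.975), sum(res@nTest), 0.5)
  expect_gte(nCorrect, ci[1]); expect_lte(nCorrect, ci[2])
})

test_that("between-day transfer reports both directions over common channels", {
  e1 <- makeTestEpochs(seed = 21, nPerMovement = 50L,
                       profile = cleanProfile(noiseRms_uV = 1))
  e2 <- makeTestEpochs(seed = 22, nPerMovement = 50L,
                       profile = cleanProfile(noiseRms_uV = 1))
  spec <- classifierSpec("slda-features")
  res <- betweenDay(e1, e2, spec)
  expect_named(accuracies(res), c("day1->day2", "day2->day1"))
  expect_equal(unname(res@nTest), c(nTrials(e2), nTrials(e1)))
  # identical-profile days transfer about as well as within-day
  expect_lte(abs(meanAccuracy(res) -
                 meanAccuracy(withinDayCV(e1, spec, seed = 1))), 0.05)
  # differing channel sets resolve to the intersection
  e2small <- ErrPDecode:::subsetEpochs(e2, channels = smallMontage()[1:7])
  expect_message(res2 <- betweenDay(e1, e2small, spec), "common channels")
  expect_true(all(accuracies(res2) >= 0 & accuracies(res2) <= 1))
  expect_error(betweenDay(ErrPDecode:::subsetEpochs(e1, integer(0)), e2,
                          spec), "epochs")
})

test_that("resubstitution is at least as good as held-out CV on clean data", {
  ep <- makeTestEpochs(seed = 25, profile = cleanProfile(noiseRms_uV = 1))
  spec <- classifierSpec("slda-features")
  resub <- betweenDay(ep, ep, spec)
  cv <- withinDayCV(ep, spec, seed = 2)
  expect_gte(meanAccuracy(resub), meanAccuracy(cv) - 1e-9)
})

test_that("leave-one-participant-out yields one accuracy per participant", {
  eps <- makeTestCohortEpochs(seed = 31, nParticipants = 3L, nDays = 1L,
                              nPerMovement = 25L)
  res <- acrossParticipantLopo(eps, classifierSpec("slda-features"))
  expect_length(accuracies(res), 3L)
  expect_named(accuracies(res), names(eps))
  expect_equal(unname(res@nTest), vapply(eps, nTrials, numeric(1)),
               ignore_attr = TRUE)
  expect_error(acrossParticipantLopo(eps[1]), "2 participants")
})

test_that("grand averages combine participant means with standard errors", {
  mk <- function(v) {
    dat <- array(v, dim = c(1, 10, 4))
    new("EpochSet", data = dat,
        labels = ErrPDecode:::errpFactor(rep(c("ErrP", "NonErrP"), 2)),
        window = c(100, 300), fs = 50, channels = "FCz",
        provenance = data.frame(participant = "p", day = 1L, trial = 1:4))
  }
  ga <- grandAverage(list(mk(1), mk(3)), "FCz", "ErrP")
  expect_equal(ga$mean, rep(2, 10))
  expect_equal(ga$se, rep(1, 10))     # SD = sqrt(2), SE = sqrt(2)/sqrt(2)
  expect_equal(ga$nParticipants, 2L)
  # single participant: zero SE
  ga1 <- grandAverage(list(mk(5)), "FCz", "ErrP")
  expect_equal(ga1$se, rep(0, 10))
  # missing channel is skipped with a message
  other <- mk(2); other@channels <- "Cz"
  expect_message(ga2 <- grandAverage(list(mk(1), other), "FCz", "ErrP"),
                 "skipped")
  expect_equal(ga2$nParticipants, 1L)
})

test_that("correlations reproduce hand-computed coefficients", {
  p <- correlateAccuracies(c(1, 2, 3), c(2, 4, 6), "pearson")
  expect_equal(p$estimate, 1)
  p2 <- correlateAccuracies(c(1, 2, 3), c(6, 4, 5), "pearson")
  expect_equal(p2$estimate, -0.5)
  s <- correlateAccuracies(c(1, 2, 3), c(6, 4, 5), "spearman")
  expect_equal(s$estimate, -0.5)      # 1 - 6*6 / (3*8)
  expect_error(correlateAccuracies(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(correlateAccuracies(1:2, 1:2), "length")
})
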