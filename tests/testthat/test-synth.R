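test_that("uncoupled oscillators relax to the limit-cycle radius", {
  sim <- simulateStuartLandau(n = 16, lambda = 2.25, omega = 6, sigma = 0,
                              P = 2, dt = 0.01, tMax = 60, seed = 4,
                              init = "random")
  aa <- aaValues(analyticAmplitude(sim$recording))
  radius <- rowMeans(aa[, 3500:5500])           # post-transient, off edges
  expect_lt(max(abs(radius - 1.5)) / 1.5, 0.01)
})

test_that("identical initial conditions stay perfectly synchronized", {
  sim <- simulateStuartLandau(n = 12, sigma = 6, P = 3, tMax = 30, seed = 1,
                              init = "identical")
  x <- recordingData(sim$recording)
  spread <- apply(x, 2, function(col) max(col) - min(col))
  expect_lt(max(spread), 1e-9)
  ae <- aeValues(amplitudeEntropy(analyticAmplitude(sim$recording),
                                  BinningSpec(0.05)))
  expect_lt(max(ae), 1e-9)
})

test_that("integration is deterministic and flags divergence", {
  a <- simulateStuartLandau(n = 8, sigma = 2, P = 2, tMax = 5, seed = 9)
  b <- simulateStuartLandau(n = 8, sigma = 2, P = 2, tMax = 5, seed = 9)
  expect_identical(recordingData(a$recording), recordingData(b$recording))
  expect_error(simulateStuartLandau(n = 8, lambda = 100, sigma = 2, P = 2,
                                    dt = 0.19, omega = 1, tMax = 50,
                                    seed = 1),
               "instability")
})

test_that("halving dt changes the post-transient envelope by well under 1%", {
  base <- slPresets()$coherent
  base$tMax <- 20
  a <- do.call(simulateStuartLandau, c(base, list(seed = 3)))
  fine <- base
  fine$dt <- base$dt / 2
  b <- do.call(simulateStuartLandau, c(fine, list(seed = 3)))
  aaA <- aaValues(analyticAmplitude(a$recording))
  aaB <- aaValues(analyticAmplitude(b$recording))[, seq(2, 4000, by = 2)]
  post <- 1100:1900
  relRms <- sqrt(mean((aaA[, post] - aaB[, post])^2)) /
    sqrt(mean(aaA[, post]^2))
  expect_lt(relRms, 0.01)
})

test_that("the surrogate generator honours its layout contract", {
  sim <- simulateSeizureSurrogate(m = 10, fs = 64, preS = 4, ictalS = 5,
                                  postS = 4, affectedFraction = 0.2,
                                  gain = 6, seed = 2)
  rec <- sim$recording
  expect_equal(nChannels(rec), 10)
  expect_equal(nSamples(rec), 13 * 64)
  expect_equal(annotation(rec)@onset, 4)
  expect_equal(annotation(rec)@offset, 9)
  expect_equal(length(affectedChannels(sim$truth)), round(10 * 0.2))
  expect_true(all(affectedChannels(sim$truth) %in% channelIds(rec)))
  expect_equal(as.integer(table(regimeLabels(sim$truth))[c("pre", "ictal",
                                                           "post")]),
               c(4, 5, 4) * 64)
  expect_error(simulateSeizureSurrogate(m = 10, affectedFraction = 0.01),
               "parameter error")

  # determinism
  sim2 <- simulateSeizureSurrogate(m = 10, fs = 64, preS = 4, ictalS = 5,
                                   postS = 4, affectedFraction = 0.2,
                                   gain = 6, seed = 2)
  expect_identical(recordingData(sim2$recording), recordingData(rec))
})

test_that("unit gain is a null generator; high gain boosts affected RMS", {
  simNull <- simulateSeizureSurrogate(m = 12, fs = 128, preS = 5, ictalS = 5,
                                      postS = 5, gain = 1, seed = 6)
  x <- recordingData(simNull$recording)
  idx <- segmentIndices(annotation(simNull$recording), 128, ncol(x))
  rmsPre <- apply(x[, idx$pre], 1, sd)
  rmsIct <- apply(x[, idx$ictal], 1, sd)
  expect_gt(rankSumTest(rmsIct, rmsPre)$p, 0.01)

  simHi <- simulateSeizureSurrogate(m = 12, fs = 128, preS = 5, ictalS = 5,
                                    postS = 5, gain = 8, seed = 6)
  xh <- recordingData(simHi$recording)
  aff <- channelIds(simHi$recording) %in% affectedChannels(simHi$truth)
  gainObs <- apply(xh[aff, idx$ictal, drop = FALSE], 1, sd) /
    apply(xh[aff, idx$pre, drop = FALSE], 1, sd)
  expect_true(all(gainObs > 2))
  unaff <- apply(xh[!aff, idx$ictal, drop = FALSE], 1, sd) /
    apply(xh[!aff, idx$pre, drop = FALSE], 1, sd)
  expect_true(all(abs(unaff - 1) < 0.5))
})

test_that("the surrogate's broadband AE rises during the seizure", {
  sim <- simulateSeizureSurrogate(m = 32, fs = 128, preS = 8, ictalS = 8,
                                  postS = 8, gain = 8, seed = 1)
  sm <- segmentMeans(computeAE(sim$recording, "broadband")$broadband)
  expect_gt(sm$meanIctal, sm$meanPre)
  expect_gt(sm$meanIctal, sm$meanPost)
})

test_that("cohorts are reproducible with the requested structure", {
  co <- makeCohort(nPatients = 4, seizuresPerPatient = c(2, 3),
                   ictalRange = c(1, 3), m = 6, fs = 64, preS = 2, postS = 2,
                   seed = 7)
  pats <- vapply(co, function(s) patientId(s$recording), character(1))
  expect_equal(sort(unique(pats)), sprintf("P%02d", 1:4))
  cnt <- table(pats)
  expect_true(all(cnt >= 2 & cnt <= 3))
  ids <- vapply(co, function(s)
    paste(patientId(s$recording), seizureId(s$recording)), character(1))
  expect_false(anyDuplicated(ids) > 0)

  co2 <- makeCohort(nPatients = 4, seizuresPerPatient = c(2, 3),
                    ictalRange = c(1, 3), m = 6, fs = 64, preS = 2, postS = 2,
                    seed = 7)
  expect_identical(lapply(co, function(s) recordingData(s$recording)),
                   lapply(co2, function(s) recordingData(s$recording)))
})
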