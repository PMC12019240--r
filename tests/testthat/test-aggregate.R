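test_that("segment means are exact on piecewise-constant series", {
  ae <- constantSegmentsSeries(pre = 1, ict = 2, post = 0.5)
  sm <- segmentMeans(ae)
  expect_equal(c(sm$meanPre, sm$meanIctal, sm$meanPost), c(1, 2, 0.5))
  expect_equal(seizureEffect(sm), 1)
  expect_equal(seizureEffect(data.frame(meanPre = 2, meanIctal = 2)), 0)

  # post window that exceeds the series is a window error
  bad <- new("AESeries", values = rep(1, 50), band = bandByName("broadband"),
             binning = BinningSpec(), fs = 10, patientId = "P",
             seizureId = "S",
             annotation = SeizureAnnotation(2, 3, preDuration = 2,
                                            postDuration = 5))
  expect_error(segmentMeans(bad), "window error")
})

test_that("NaN padding sits between each seizure's end and the common post block", {
  fs <- 10
  mk <- function(ictS, patient, seizure = "S1")
    constantSegmentsSeries(fs = fs, preS = 2, ictS = ictS, postS = 2,
                           patient = patient, seizure = seizure)
  al <- nanPadAlign(list(mk(5, "A"), mk(8, "B")))
  v <- alignedValues(al)
  expect_equal(dim(v), c(2, (2 + 8 + 2) * fs))
  # row 1: exactly 3 s * fs NaNs between its ictal end and the post block
  expect_equal(sum(is.nan(v[1, ])), 3 * fs)
  expect_true(all(is.nan(v[1, (2 + 5) * fs + seq_len(3 * fs)])))
  expect_false(anyNA(v[2, ]))
  # finite-entry conservation: nothing lost, nothing invented
  expect_equal(sum(is.finite(v)), (2 + 5 + 2) * fs + (2 + 8 + 2) * fs)

  # single series: no padding at all
  single <- nanPadAlign(list(mk(5, "A")))
  expect_false(anyNA(alignedValues(single)))
  expect_equal(ncol(alignedValues(single)), (2 + 5 + 2) * fs)
})

test_that("contributing-row counts are non-increasing across the ictal block", {
  set.seed(31)
  for (rep in 1:10) {
    lens <- sample(3:12, 5, replace = TRUE)
    sl <- lapply(seq_along(lens), function(i)
      constantSegmentsSeries(fs = 5, preS = 1, ictS = lens[i], postS = 1,
                             patient = sprintf("P%d", i)))
    al <- nanPadAlign(sl)
    ict <- alignedValues(al)[, al@preLen + seq_len(al@ictalLen), drop = FALSE]
    counts <- colSums(is.finite(ict))
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[1], 5)
  }
})

test_that("two-step averaging weights patients equally, not seizures", {
  fs <- 10
  mkConst <- function(val, patient, seizure) {
    s <- constantSegmentsSeries(pre = val, ict = val, post = val, fs = fs,
                                preS = 1, ictS = 2, postS = 1,
                                patient = patient, seizure = seizure)
    s
  }
  al <- nanPadAlign(list(mkConst(1, "A", "S1"), mkConst(1, "A", "S2"),
                         mkConst(3, "B", "S1")))
  ga <- twoStepAverage(al)
  # pooled mean would be 5/3; equal patient weighting gives 2
  expect_equal(ga$mean, rep(2, length(ga$mean)))
  expect_equal(ga$nPatients, 2)
  expect_equal(unname(ga$sd), rep(sd(c(1, 3)), length(ga$sd)))

  # duplicating a patient's identical seizure list changes nothing
  al2 <- nanPadAlign(list(mkConst(1, "A", "S1"), mkConst(1, "A", "S2"),
                          mkConst(1, "A", "S3"), mkConst(1, "A", "S4"),
                          mkConst(3, "B", "S1")))
  expect_equal(twoStepAverage(al2)$mean, ga$mean)
})

test_that("two-step average equals the brute-force double loop on ragged input", {
  set.seed(59)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    pats <- sample(sprintf("P%d", 1:3), n, replace = TRUE)
    mat <- matrix(rnorm(n * 30), n, 30)
    for (r in seq_len(n)) {
      k <- sample(0:10, 1)
      if (k > 0) mat[r, sample(10:25, k)] <- NaN
    }
    al <- new("AlignedAE", values = cbind(matrix(rnorm(n * 2), n, 2), mat,
                                          matrix(rnorm(n * 2), n, 2)),
              preLen = 2L, ictalLen = 30L, postLen = 2L, patientIds = pats,
              seizureIds = sprintf("S%d", seq_len(n)), fs = 1)
    expect_equal(twoStepAverage(al)$mean,
                 bruteTwoStep(alignedValues(al), pats), tolerance = 1e-12)
  }
})

test_that("time normalization resamples the ictal block linearly", {
  fs <- 10
  ramp <- new("AESeries",
              values = c(rep(0, 20), seq(0, 1, length.out = 30), rep(1, 20)),
              band = bandByName("broadband"), binning = BinningSpec(),
              fs = fs, patientId = "P", seizureId = "S",
              annotation = SeizureAnnotation(2, 5, 2, 2))
  tn <- timeNormalize(ramp, 11)
  idx <- segmentIndices(annotation(tn), fs, nSamples(tn))
  expect_equal(aeValues(tn)[idx$ictal], seq(0, 1, by = 0.1), tolerance = 1e-12)
  # identity when the target length matches
  same <- timeNormalize(ramp, 30)
  expect_equal(aeValues(same), aeValues(ramp), tolerance = 1e-12)
  expect_error(timeNormalize(ramp, 1), "parameter error")

  # mean preservation for a smooth series
  smooth <- new("AESeries",
                values = c(rep(0.5, 20), 1 + sin(seq(0, pi, length.out = 200)),
                           rep(0.5, 20)),
                band = bandByName("broadband"), binning = BinningSpec(),
                fs = 10, patientId = "P", seizureId = "S",
                annotation = SeizureAnnotation(2, 22, 2, 2))
  idx0 <- segmentIndices(annotation(smooth), 10, nSamples(smooth))
  m0 <- mean(aeValues(smooth)[idx0$ictal])
  tn2 <- timeNormalize(smooth, 50)
  idx2 <- segmentIndices(annotation(tn2), 10, nSamples(tn2))
  m2 <- mean(aeValues(tn2)[idx2$ictal])
  expect_lt(abs(m2 - m0) / m0, 0.05)
})

test_that("NaN padding and time normalization agree on constant-AE inputs", {
  mk <- function(ictS, patient)
    constantSegmentsSeries(pre = 1.2, ict = 2.4, post = 0.8, fs = 10,
                           preS = 2, ictS = ictS, postS = 2, patient = patient)
  sl <- list(mk(4, "A"), mk(9, "B"), mk(6, "C"))
  padded <- twoStepAverage(nanPadAlign(sl))$mean
  norm <- twoStepAverage(nanPadAlign(lapply(sl, timeNormalize,
                                            nIctal = 60)))$mean
  # both routes recover the same piecewise-constant grand profile
  expect_equal(unique(round(padded, 12)), c(1.2, 2.4, 0.8))
  expect_equal(unique(round(norm, 12)), c(1.2, 2.4, 0.8))
})

test_that("pmf snapshots are normalized and consistent with the entropy", {
  set.seed(9)
  mat <- matrix(abs(rnorm(16 * 40, 50, 25)), 16, 40)
  aa <- new("AAMatrix", values = mat, band = bandByName("broadband"),
            fs = 10, patientId = "P", seizureId = "S",
            annotation = SeizureAnnotation())
  snap <- aaPmfAt(aa, 1.5, BinningSpec(10))
  expect_equal(sum(snap@masses), 1, tolerance = 1e-12)
  h <- -sum(snap@masses[snap@masses > 0] * log(snap@masses[snap@masses > 0]))
  expect_equal(h, amplitudeEntropyAt(mat[, 16], BinningSpec(10)),
               tolerance = 1e-12)
  expect_error(aaPmfAt(aa, 99, BinningSpec(10)), "window error")

  # constant column: unit mass in one bin
  cst <- new("AAMatrix", values = matrix(5, 4, 10),
             band = bandByName("broadband"), fs = 10, patientId = "P",
             seizureId = "S", annotation = SeizureAnnotation())
  expect_equal(aaPmfAt(cst, 0, BinningSpec(10))@masses, 1)

  # grand average of identical snapshots is idempotent
  ga <- pmfGrandAverage(list(snap, snap), c("A", "B"))
  expect_equal(sum(ga@masses), 1, tolerance = 1e-12)
  expect_equal(ga@masses[ga@masses > 0], snap@masses[snap@masses > 0],
               tolerance = 1e-12)
})
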