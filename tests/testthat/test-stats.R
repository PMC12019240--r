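test_that("the Bonferroni threshold is a plain division", {
  expect_equal(bonferroniThreshold(0.05, 18), 0.05 / 18)
  expect_equal(round(bonferroniThreshold(0.05, 18), 5), 0.00278)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.01, 4), 0.0025)
})

test_that("segment tables validate their shape", {
  set.seed(1)
  tab <- simulateSegmentTable(nPatients = 3, nSeizures = 2)
  expect_silent(validateSegmentTable(tab))
  expect_error(validateSegmentTable(tab[-1, ]), "exactly 3 rows")
  bad <- tab
  bad$segment <- as.character(bad$segment)
  bad$segment[1] <- "during"
  expect_error(validateSegmentTable(bad), "pre/ictal/post")
})

test_that("a noiseless segment table is recovered exactly", {
  rows <- expand.grid(patientId = c("P1", "P2", "P3"),
                      seizureId = c("S1", "S2"),
                      segment = c("pre", "ictal", "post"),
                      stringsAsFactors = FALSE)
  rows$band <- "broadband"
  rows$meanAe <- ifelse(rows$segment == "ictal", 2.3, 1.5)
  fit <- suppressWarnings(fitSegmentModel(rows, "broadband"))
  expect_equal(fit$estimate[fit$term == "pre"], -0.8, tolerance = 1e-6)
  expect_equal(fit$estimate[fit$term == "post"], -0.8, tolerance = 1e-6)
})

test_that("the mixed model recovers a known ictal effect", {
  set.seed(2024)
  tab <- simulateSegmentTable(nPatients = 16, nSeizures = 6,
                              ictalEffect = 0.8)
  fit <- fitSegmentModel(tab, "broadband")
  expect_equal(fit$estimate[fit$term == "pre"], -0.8, tolerance = 0.1)
  expect_lt(fit$p[fit$term == "pre"], bonferroniThreshold(0.05, 18))
  expect_true(all(fit$se > 0))
  # Wald p monotone in |estimate|/se
  z <- abs(fit$estimate) / fit$se
  expect_true(all(diff(fit$p[order(-z)]) >= -1e-15))
})

test_that("estimates are invariant to relabeling patients", {
  set.seed(7)
  tab <- simulateSegmentTable(nPatients = 8, nSeizures = 3)
  fit1 <- fitSegmentModel(tab, "broadband")
  perm <- sample(unique(tab$patientId))
  names(perm) <- unique(tab$patientId)
  tab2 <- tab
  tab2$patientId <- unname(perm[tab$patientId])
  fit2 <- fitSegmentModel(tab2, "broadband")
  expect_equal(fit1$estimate, fit2$estimate, tolerance = 1e-8)
  expect_equal(fit1$p, fit2$p, tolerance = 1e-6)
})

test_that("degenerate designs error or warn as contracted", {
  set.seed(3)
  tab <- simulateSegmentTable(nPatients = 1, nSeizures = 4)
  expect_error(fitSegmentModel(tab, "broadband"), "2 patients")
  # identical per-patient profiles force zero between-patient variance
  eps <- matrix(rnorm(6, 0, 0.1), 2, 3)
  flat <- do.call(rbind, lapply(1:4, function(p)
    do.call(rbind, lapply(1:2, function(s)
      data.frame(patientId = sprintf("P%d", p),
                 seizureId = sprintf("S%d", s), band = "broadband",
                 segment = c("pre", "ictal", "post"),
                 meanAe = 1.5 + c(0, 0.8, 0) + eps[s, ])))))
  expect_warning(fitSegmentModel(flat, "broadband"), "singular")
})

test_that("the per-band report applies the family-wide threshold", {
  set.seed(11)
  tabs <- do.call(rbind, lapply(c("delta", "beta"), function(b)
    simulateSegmentTable(nPatients = 10, nSeizures = 3, ictalEffect = 0.8,
                         band = b)))
  rep <- suppressWarnings(segmentEffectReport(tabs))
  expect_equal(attr(rep, "threshold"), 0.05 / 6)   # 3 comparisons x 2 bands
  expect_true(all(rep$significant == (rep$p < 0.05 / 6)))
  expect_setequal(unique(rep$band), c("delta", "beta"))
})

test_that("rank correlation equals the rank-then-Pearson oracle", {
  expect_equal(rankCorrelation(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(rankCorrelation(1:4, c(8, 6, 4, 2))$rho, -1)
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(8)
    y <- rnorm(8)
    rc <- rankCorrelation(x, y)
    # independent oracle: rank then textbook Pearson formula
    rx <- rank(x); ry <- rank(y)
    num <- sum((rx - mean(rx)) * (ry - mean(ry)))
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(rc$rho, num / den, tolerance = 1e-12)
    expect_equal(rc$rho, suppressWarnings(
      cor.test(x, y, method = "spearman")$estimate[[1]]), tolerance = 1e-12)
  }
  expect_error(rankCorrelation(rep(1, 5), 1:5), "undefined correlation")
  expect_error(rankCorrelation(1:3, 1:3), "at least 4")
})

test_that("rank-sum p-values match exact enumeration on tiny samples", {
  rs <- rankSumTest(c(1, 2), c(10, 11))
  expect_equal(rs$p, 1 / 3, tolerance = 1e-12)
  expect_equal(rs$method, "exact")
  expect_equal(rs$statistic, 3)   # ranks 1 + 2

  # brute-force enumeration over all C(5,2) assignments for another case
  a <- c(1, 5); b <- c(2, 3, 4)
  rs2 <- rankSumTest(a, b)
  allW <- combn(5, 2, sum)
  obsW <- sum(rank(c(a, b))[1:2])
  pBrute <- mean(abs(allW - mean(allW)) >= abs(obsW - mean(allW)))
  expect_equal(rs2$p, pBrute, tolerance = 1e-12)

  # identical tied samples carry no evidence
  expect_equal(rankSumTest(c(1, 2), c(1, 2))$p, 1)

  # clearly shifted Gaussians are detected one-sided
  set.seed(33)
  g1 <- rnorm(20, 2, 1); g2 <- rnorm(20, 0, 1)
  det <- rankSumTest(g1, g2, sided = "one-greater")
  expect_lt(det$p, 0.05)
  expect_equal(det$method, "normal-approximation")
})
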