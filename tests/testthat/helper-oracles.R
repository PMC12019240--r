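# Independent brute-force reference implementations used as oracles.
# These deliberately use explicit loops and literal histograms, sharing no
# code with the package internals.

# entropy of one amplitude vector, straight from the definition
bruteAEAt <- function(aa, dbin = 10, base2 = FALSE) {
  mn <- min(aa)
  mx <- max(aa)
  B <- floor((mx - mn) / dbin) + 1
  counts <- rep(0, B)
  for (v in aa) {
    k <- floor((v - mn) / dbin) + 1
    if (k > B) k <- B              # right-closed last bin
    counts[k] <- counts[k] + 1
  }
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / length(aa)
      h <- h - p * log(p)
    }
  }
  if (base2) h / log(2) else h
}

# double loop over time points
bruteAESeries <- function(mat, dbin = 10, base2 = FALSE) {
  out <- numeric(ncol(mat))
  for (t in seq_len(ncol(mat))) out[t] <- bruteAEAt(mat[, t], dbin, base2)
  out
}

# two-loop NaN-skipping two-step average
bruteTwoStep <- function(mat, patientIds) {
  pats <- unique(patientIds)
  pm <- matrix(NA_real_, length(pats), ncol(mat))
  for (p in seq_along(pats)) {
    rows <- which(patientIds == pats[p])
    for (j in seq_len(ncol(mat))) {
      vals <- c()
      for (r in rows) if (is.finite(mat[r, j])) vals <- c(vals, mat[r, j])
      pm[p, j] <- if (length(vals)) sum(vals) / length(vals) else NaN
    }
  }
  grand <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    vals <- c()
    for (p in seq_along(pats)) if (is.finite(pm[p, j]))
      vals <- c(vals, pm[p, j])
    grand[j] <- if (length(vals)) sum(vals) / length(vals) else NaN
  }
  grand
}

# a small annotated AE series with piecewise-constant values
constantSegmentsSeries <- function(pre = 1, ict = 2, post = 0.5,
                                   fs = 10, preS = 2, ictS = 3, postS = 2,
                                   patient = "P1", seizure = "S1") {
  vals <- c(rep(pre, preS * fs), rep(ict, ictS * fs), rep(post, postS * fs))
  new("AESeries", values = vals, band = bandByName("broadband"),
      binning = BinningSpec(), fs = fs, patientId = patient,
      seizureId = seizure,
      annotation = SeizureAnnotation(preS, preS + ictS,
                                     preDuration = preS, postDuration = postS))
}

# simulated long-format segment table with known ictal effect
simulateSegmentTable <- function(nPatients = 16, nSeizures = 6,
                                 ictalEffect = 0.8, interceptSD = 0.2,
                                 residSD = 0.1, baseline = 1.5,
                                 band = "broadband") {
  rows <- list()
  for (p in seq_len(nPatients)) {
    u <- rnorm(1, 0, interceptSD)
    for (s in seq_len(nSeizures)) {
      for (seg in c("pre", "ictal", "post")) {
        mu <- baseline + u + if (seg == "ictal") ictalEffect else 0
        rows[[length(rows) + 1]] <- data.frame(
          patientId = sprintf("P%02d", p), seizureId = sprintf("S%02d", s),
          band = band, segment = seg, meanAe = mu + rnorm(1, 0, residSD))
      }
    }
  }
  do.call(rbind, rows)
}

expect_no_nan <- function(x) expect_true(all(is.finite(x)))
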