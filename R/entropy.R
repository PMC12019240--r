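#' Fixed-width bin memberships of cross-channel amplitudes
#'
#' Bins the m analytic amplitudes observed across channels at one time
#' point into intervals of fixed width `binWidth`, with the edge grid
#' anchored at the cross-channel minimum: B = floor((max - min)/width) + 1
#' bins, bin k spanning [min + k*width, min + (k+1)*width) half-open, the
#' last bin right-closed so the maximum is always assignable. A degenerate
#' range (max = min) gives a single bin.
#'
#' @param aa numeric vector of m >= 2 finite, non-negative amplitudes.
#' @param spec a [BinningSpec-class].
#' @return A list with `bins` (1-based bin index per channel), `counts`
#'   (length B occupancy), `B` (bin count) and `edges` (the B + 1 bin
#'   edges).
#' @examples
#' binMemberships(c(0, 5, 12, 31), BinningSpec(binWidth = 10))
#' @export
binMemberships <- function(aa, spec = BinningSpec()) {
  checkAmplitudeVector(aa)
  mn <- min(aa)
  B <- as.integer(floor((max(aa) - mn) / spec@binWidth)) + 1L
  bins <- pmin.int(floor((aa - mn) / spec@binWidth), B - 1L) + 1L
  list(bins = as.integer(bins), counts = tabulate(bins, B), B = B,
       edges = mn + (0:B) * spec@binWidth)
}

#' Amplitude entropy at a single time point
#'
#' Shannon entropy of the binned cross-channel amplitude distribution:
#' p_i = #\{j : b_j = i\} / m over the bins of [binMemberships()], and
#' AE = -sum_i p_i log p_i with the convention 0 log 0 = 0 (empty bins
#' contribute exactly nothing, which is what makes the measure robust to
#' single far outliers widening the bin range). Natural log by default
#' (nats); base 2 (bits) via the spec. The result lies in
#' [0, log min(m, B)].
#'
#' @inheritParams binMemberships
#' @return A single non-negative entropy value.
#' @examples
#' amplitudeEntropyAt(c(0, 5, 12, 31), BinningSpec(10))   # 1.0397 nats
#' amplitudeEntropyAt(c(7, 7, 7), BinningSpec(10))        # 0
#' amplitudeEntropyAt(c(0, 11, 22, 33), BinningSpec(10))  # log(4)
#' @export
amplitudeEntropyAt <- function(aa, spec = BinningSpec()) {
  bm <- binMemberships(aa, spec)
  p <- bm$counts[bm$counts > 0L] / length(aa)
  h <- -sum(p * log(p))
  if (spec@logBase == "2") h / log(2) else h
}

#' Amplitude-entropy time series of an envelope matrix
#'
#' Applies the per-time-point entropy to every column of an analytic
#' amplitude matrix. With the default `rangeMode = "timepoint"` the bin
#' grid is re-anchored at each column's minimum (the operational
#' definition); with `"global"` one grid spanning the whole recording's
#' amplitude range is used for every column.
#'
#' @param aa an [AAMatrix-class].
#' @param spec a [BinningSpec-class].
#' @return An [AESeries-class] of length `nSamples(aa)` carrying band,
#'   binning and annotation through.
#' @examples
#' rec <- SeizureRecording(matrix(abs(rnorm(8 * 100, 50, 20)), 8, 100),
#'                         fs = 100)
#' ae <- amplitudeEntropy(analyticAmplitude(rec))
#' @export
amplitudeEntropy <- function(aa, spec = BinningSpec()) {
  stopifnot(is(aa, "AAMatrix"), is(spec, "BinningSpec"))
  validObject(spec)
  v <- aaValues(aa)
  m <- nrow(v)
  if (m < 2L) stop("data error: need at least 2 channels", call. = FALSE)
  Tn <- ncol(v)
  w <- spec@binWidth

  rows <- asplit(v, 1L)
  if (spec@rangeMode == "timepoint") {
    mn <- Reduce(pmin.int, rows)
    mx <- Reduce(pmax.int, rows)
  } else {
    mn <- rep(min(v), Tn)
    mx <- rep(max(v), Tn)
  }
  B <- floor((mx - mn) / w) + 1
  Bmax <- max(B)

  if (is.finite(Bmax) && Tn * Bmax <= 2e8) {
    bmat <- floor((v - matrix(mn, m, Tn, byrow = TRUE)) / w)
    bmat <- pmin(bmat, matrix(B - 1, m, Tn, byrow = TRUE))
    key <- (col(bmat) - 1) * Bmax + bmat + 1
    cnt <- tabulate(key, Tn * Bmax)
    nz <- which(cnt > 0L)
    colid <- (nz - 1) %/% Bmax + 1
    s <- rowsum(cnt[nz] * log(cnt[nz]), colid)
    h <- log(m) - as.numeric(s) / m
  } else {
    h <- vapply(seq_len(Tn), function(t) {
      bins <- pmin.int(floor((v[, t] - mn[t]) / w), B[t] - 1)
      p <- tabulate(bins + 1L, B[t])
      p <- p[p > 0L] / m
      -sum(p * log(p))
    }, numeric(1))
  }
  h <- pmax(h, 0)                      # clip tiny negative rounding noise
  if (spec@logBase == "2") h <- h / log(2)
  new("AESeries", values = h, band = bandOf(aa), binning = spec,
      fs = samplingRate(aa), patientId = patientId(aa),
      seizureId = seizureId(aa), annotation = annotation(aa))
}

checkAmplitudeVector <- function(aa) {
  if (length(aa) < 2L)
    stop("data error: need at least 2 channels", call. = FALSE)
  if (any(!is.finite(aa)))
    stop("data error: non-finite amplitude value", call. = FALSE)
  if (any(aa < 0))
    stop("data error: negative amplitude value", call. = FALSE)
  invisible(TRUE)
}
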