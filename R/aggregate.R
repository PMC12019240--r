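#' Per-segment mean amplitude entropy of one seizure
#'
#' Arithmetic mean of the AE series over the three half-open annotation
#' windows [onset - preDuration, onset), [onset, offset) and
#' [offset, offset + postDuration) (in samples, see [segmentIndices()]).
#'
#' @param ae an [AESeries-class] with a seizure annotation.
#' @return A one-row data.frame with columns `patientId`, `seizureId`,
#'   `band`, `meanPre`, `meanIctal`, `meanPost` -- the per-seizure atom of
#'   all downstream statistics.
#' @export
segmentMeans <- function(ae) {
  stopifnot(is(ae, "AESeries"))
  idx <- segmentIndices(annotation(ae), samplingRate(ae), nSamples(ae))
  v <- aeValues(ae)
  data.frame(patientId = patientId(ae), seizureId = seizureId(ae),
             band = bandOf(ae)@name,
             meanPre = mean(v[idx$pre]), meanIctal = mean(v[idx$ictal]),
             meanPost = mean(v[idx$post]), stringsAsFactors = FALSE)
}

#' Seizure effect: ictal minus pre-seizure mean AE
#'
#' @param summary a data.frame as returned by [segmentMeans()] (any number
#'   of rows).
#' @return Numeric vector `meanIctal - meanPre`, one value per row.
#' @examples
#' seizureEffect(data.frame(meanPre = 1, meanIctal = 2))   # 1
#' @export
seizureEffect <- function(summary) {
  stopifnot(all(c("meanPre", "meanIctal") %in% names(summary)))
  summary$meanIctal - summary$meanPre
}

#' Align variable-length seizures by NaN padding
#'
#' Lays out each seizure's AE series as [pre | ictal | NaN padding | post]:
#' all rows share the common pre length, each ictal block is padded with
#' NaN up to the longest seizure, and the post blocks start together at
#' column preLen + maxIctalLen. Column-wise, the number of contributing
#' (finite) rows is therefore non-increasing across the ictal block --
#' beyond the shortest seizure fewer and fewer seizures contribute, until
#' only the longest does.
#'
#' @param seriesList a list of [AESeries-class] objects sharing the same
#'   sampling rate and pre/post window durations.
#' @return An [AlignedAE-class].
#' @export
nanPadAlign <- function(seriesList) {
  stopifnot(is.list(seriesList), length(seriesList) >= 1L)
  stopifnot(all(vapply(seriesList, is, logical(1), "AESeries")))
  fs <- vapply(seriesList, samplingRate, numeric(1))
  if (length(unique(fs)) != 1L)
    stop("alignment error: mixed sampling rates", call. = FALSE)
  fs <- fs[1]
  idx <- lapply(seriesList, function(s)
    segmentIndices(annotation(s), samplingRate(s), nSamples(s)))
  preLens <- vapply(idx, function(i) length(i$pre), integer(1))
  postLens <- vapply(idx, function(i) length(i$post), integer(1))
  if (length(unique(preLens)) != 1L || length(unique(postLens)) != 1L)
    stop("alignment error: mixed pre/post window durations", call. = FALSE)
  preLen <- preLens[1]; postLen <- postLens[1]
  ictalLens <- vapply(idx, function(i) length(i$ictal), integer(1))
  maxIctal <- max(ictalLens)
  out <- matrix(NaN, length(seriesList), preLen + maxIctal + postLen)
  for (r in seq_along(seriesList)) {
    v <- aeValues(seriesList[[r]])
    out[r, seq_len(preLen)] <- v[idx[[r]]$pre]
    out[r, preLen + seq_len(ictalLens[r])] <- v[idx[[r]]$ictal]
    out[r, preLen + maxIctal + seq_len(postLen)] <- v[idx[[r]]$post]
  }
  new("AlignedAE", values = out, preLen = preLen,
      ictalLen = as.integer(maxIctal), postLen = postLen,
      patientIds = vapply(seriesList, patientId, character(1)),
      seizureIds = vapply(seriesList, seizureId, character(1)), fs = fs)
}

#' Two-step (seizure, then patient) grand average
#'
#' Step 1 takes, per patient, the NaN-skipping column mean over that
#' patient's seizures; step 2 takes the plain column mean over the patient
#' means (NaN where no patient contributes). Every patient therefore
#' contributes with equal weight regardless of how many seizures they have.
#' The spread series is the standard deviation across the patient means.
#'
#' @param aligned an [AlignedAE-class].
#' @return A list with `mean` (grand-mean AE series), `sd` (across-patient
#'   SD series), `nPatients`, and `patientMeans` (patients x time matrix).
#' @examples
#' # a patient with two identical seizures counts once, not twice
#' @export
twoStepAverage <- function(aligned) {
  stopifnot(is(aligned, "AlignedAE"))
  v <- alignedValues(aligned)
  pats <- unique(aligned@patientIds)
  pm <- matrix(NaN, length(pats), ncol(v), dimnames = list(pats, NULL))
  for (p in seq_along(pats)) {
    rows <- v[aligned@patientIds == pats[p], , drop = FALSE]
    cnt <- colSums(is.finite(rows))
    s <- colSums(rows, na.rm = TRUE)
    pm[p, ] <- ifelse(cnt > 0, s / cnt, NaN)
  }
  cnt <- colSums(is.finite(pm))
  grand <- ifelse(cnt > 0, colSums(pm, na.rm = TRUE) / cnt, NaN)
  sdv <- vapply(seq_len(ncol(pm)), function(j) {
    x <- pm[, j][is.finite(pm[, j])]
    if (length(x) >= 2) stats::sd(x) else if (length(x) == 1) 0 else NaN
  }, numeric(1))
  list(mean = grand, sd = sdv, nPatients = length(pats), patientMeans = pm)
}

#' Resample the ictal block to a fixed number of points
#'
#' The time-normalization alternative to NaN padding: the ictal AE block is
#' linearly interpolated onto `nIctal` equally spaced points (endpoints
#' preserved exactly); pre and post blocks are untouched. The annotation is
#' adjusted so the resampled series remains consistent at the original
#' sampling rate.
#'
#' @param ae an [AESeries-class] whose ictal block has >= 2 samples.
#' @param nIctal target number of ictal samples (>= 2).
#' @return An [AESeries-class] with the ictal block resampled.
#' @export
timeNormalize <- function(ae, nIctal) {
  stopifnot(is(ae, "AESeries"))
  if (!is.numeric(nIctal) || length(nIctal) != 1L || nIctal < 2)
    stop("parameter error: nIctal must be a single integer >= 2",
         call. = FALSE)
  nIctal <- as.integer(nIctal)
  fs <- samplingRate(ae)
  idx <- segmentIndices(annotation(ae), fs, nSamples(ae))
  if (length(idx$ictal) < 2L)
    stop("length error: ictal block must have at least 2 samples",
         call. = FALSE)
  v <- aeValues(ae)
  ict <- v[idx$ictal]
  res <- if (nIctal == length(ict)) ict else
    stats::approx(seq_along(ict), ict, n = nIctal)$y
  newv <- c(v[seq_len(idx$pre[1] - 1L)], v[idx$pre], res, v[idx$post],
            v[seq(idx$post[length(idx$post)] + 1L,
                  length.out = max(0L, length(v) - idx$post[length(idx$post)]))])
  ann <- annotation(ae)
  onset0 <- floor(ann@onset * fs) / fs            # snap to the sample grid
  newAnn <- SeizureAnnotation(onset0, onset0 + nIctal / fs,
                              preDuration = ann@preDuration,
                              postDuration = ann@postDuration)
  new("AESeries", values = newv, band = bandOf(ae), binning = binningOf(ae),
      fs = fs, patientId = patientId(ae), seizureId = seizureId(ae),
      annotation = newAnn)
}

#' Cross-channel amplitude probability mass at one time point
#'
#' The binned pmf of the analytic amplitude across channels at time `tS`
#' seconds -- exactly the distribution whose Shannon entropy
#' [amplitudeEntropyAt()] reports.
#'
#' @param aa an [AAMatrix-class].
#' @param tS time in seconds (sample index `floor(tS * fs)`, 0-based).
#' @param spec a [BinningSpec-class].
#' @param label snapshot label, e.g. "T1".
#' @return A [PMFSnapshot-class].
#' @export
aaPmfAt <- function(aa, tS, spec = BinningSpec(), label = "T") {
  stopifnot(is(aa, "AAMatrix"))
  k <- floor(tS * samplingRate(aa))
  if (is.na(k) || k < 0 || k >= nSamples(aa))
    stop(sprintf("window error: time %g s outside the recording", tS),
         call. = FALSE)
  bm <- binMemberships(aaValues(aa)[, k + 1L], spec)
  new("PMFSnapshot", masses = bm$counts / sum(bm$counts),
      leftEdges = bm$edges[-length(bm$edges)], binWidth = spec@binWidth,
      label = label, timeS = tS)
}

#' Two-step grand average of pmf snapshots
#'
#' Maps each snapshot onto a common bin grid (same width, anchored at the
#' smallest left edge; masses reassigned by bin centre), averages first
#' across each patient's seizures and then across patients, and
#' renormalizes to sum 1.
#'
#' @param snapshots a list of [PMFSnapshot-class] objects with equal bin
#'   width.
#' @param patientIds character vector, one per snapshot.
#' @param label label for the averaged snapshot.
#' @return A [PMFSnapshot-class] on the common grid.
#' @export
pmfGrandAverage <- function(snapshots, patientIds = rep("P0", length(snapshots)),
                            label = "grand") {
  stopifnot(is.list(snapshots), length(snapshots) >= 1L,
            length(patientIds) == length(snapshots))
  w <- vapply(snapshots, function(s) s@binWidth, numeric(1))
  if (max(w) - min(w) > 1e-12)
    stop("alignment error: snapshots use different bin widths", call. = FALSE)
  w <- w[1]
  gmin <- min(vapply(snapshots, function(s) s@leftEdges[1], numeric(1)))
  gmax <- max(vapply(snapshots, function(s) s@leftEdges[length(s@leftEdges)],
                     numeric(1)))
  B <- as.integer(floor((gmax + w / 2 - gmin) / w)) + 1L
  onGrid <- vapply(snapshots, function(s) {
    idx <- pmin.int(floor((s@leftEdges + w / 2 - gmin) / w), B - 1L) + 1L
    vec <- numeric(B)
    for (i in seq_along(idx)) vec[idx[i]] <- vec[idx[i]] + s@masses[i]
    vec
  }, numeric(B))
  onGrid <- matrix(onGrid, nrow = B)        # B x nSnapshots
  pats <- unique(patientIds)
  pm <- vapply(pats, function(p)
    rowMeans(onGrid[, patientIds == p, drop = FALSE]), numeric(B))
  avg <- rowMeans(matrix(pm, nrow = B))
  new("PMFSnapshot", masses = avg / sum(avg),
      leftEdges = gmin + (seq_len(B) - 1L) * w, binWidth = w,
      label = label, timeS = NA_real_)
}
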