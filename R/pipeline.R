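#' Compute amplitude-entropy series for one or more bands
#'
#' Full per-recording pipeline: band-pass filter (skipped for broadband),
#' Hilbert envelope, per-time-point entropy.
#'
#' @param rec a [SeizureRecording-class].
#' @param bands character vector of band tokens ([bandByName()]) or a list
#'   of [FrequencyBand-class] objects.
#' @param spec a [BinningSpec-class].
#' @return A named list of [AESeries-class], one per band.
#' @examples
#' sim <- simulateSeizureSurrogate(m = 8, fs = 128, preS = 4, ictalS = 4,
#'                                 postS = 4, seed = 1)
#' ae <- computeAE(sim$recording, "broadband")
#' segmentMeans(ae$broadband)
#' @export
computeAE <- function(rec, bands = "broadband", spec = BinningSpec()) {
  if (is.character(bands)) bands <- lapply(bands, bandByName)
  res <- lapply(bands, function(b) amplitudeEntropy(computeAA(rec, b), spec))
  names(res) <- vapply(bands, function(b)
    if (is.character(b)) b else b@name, character(1))
  res
}

#' Run the full pipeline over a surrogate cohort
#'
#' For every seizure recording in a cohort and every requested band,
#' computes the AE series and its per-segment means, returning the
#' long-format segment table that feeds the mixed-effects test, and
#' (optionally) the per-band NaN-padded alignment and two-step grand
#' averages.
#'
#' @param cohort a list as returned by [makeCohort()] (elements with a
#'   `recording`), or a plain list of [SeizureRecording-class] objects.
#' @param bands band tokens (default "broadband").
#' @param spec a [BinningSpec-class].
#' @param keepSeries also return the AE series and grand averages
#'   (default TRUE; set FALSE to save memory on large cohorts).
#' @return A list with `segmentTable` (long format, all bands),
#'   `summaries` (wide per-seizure rows), and if `keepSeries` is TRUE
#'   `grand` (per band: the [twoStepAverage()] result).
#' @export
cohortPipeline <- function(cohort, bands = "broadband",
                           spec = BinningSpec(), keepSeries = TRUE) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  recs <- lapply(cohort, function(el)
    if (is(el, "SeizureRecording")) el else el$recording)
  bandNames <- vapply(bands, function(b)
    if (is.character(b)) b else b@name, character(1))
  summaries <- NULL
  seriesByBand <- stats::setNames(
    replicate(length(bandNames), vector("list", length(recs)),
              simplify = FALSE), bandNames)
  for (i in seq_along(recs)) {
    aeList <- computeAE(recs[[i]], bands, spec)
    for (b in bandNames) {
      summaries <- rbind(summaries, segmentMeans(aeList[[b]]))
      if (keepSeries) seriesByBand[[b]][[i]] <- aeList[[b]]
    }
  }
  out <- list(segmentTable = segmentTableFromSummaries(summaries),
              summaries = summaries)
  if (keepSeries) {
    out$grand <- lapply(seriesByBand, function(sl)
      twoStepAverage(nanPadAlign(sl)))
  }
  out
}
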