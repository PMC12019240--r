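#' Analytic amplitude (Hilbert envelope) of a recording
#'
#' Computes, per channel, the magnitude of the analytic signal
#' z(t) = x(t) + i H{x(t)}, i.e. the instantaneous amplitude
#' |z(t)| = sqrt(x(t)^2 + H{x(t)}^2) -- the positive envelope tracing the
#' peaks of the (filtered) signal. The analytic signal is built with the
#' standard frequency-domain construction (zero the negative frequencies,
#' double the positive ones) over the full recording at once, before any
#' segmentation; no windowing or overlap is applied and edge samples are
#' not trimmed here -- the annotated segment windows used downstream
#' exclude the recording edges by construction.
#'
#' @param rec a [SeizureRecording-class] (already filtered, or broadband).
#' @param band the [FrequencyBand-class] label to record on the result
#'   (default broadband); purely metadata, no filtering happens here.
#' @return An [AAMatrix-class] with non-negative envelope values, same
#'   shape as the recording.
#' @seealso [computeAA()] for the filter-then-envelope convenience wrapper.
#' @examples
#' fs <- 512; t <- seq(0, 2 - 1/fs, by = 1/fs)
#' rec <- SeizureRecording(rbind(a = 3 * cos(2*pi*10*t),
#'                               b = 2 * sin(2*pi*10*t)), fs = fs)
#' aa <- analyticAmplitude(rec)
#' range(aaValues(aa)[, 200:800])   # close to the tone amplitudes
#' @export
analyticAmplitude <- function(rec, band = bandByName("broadband")) {
  stopifnot(is(rec, "SeizureRecording"))
  if (is.character(band)) band <- bandByName(band)
  d <- recordingData(rec)
  if (ncol(d) < 1L) stop("length error: empty signal", call. = FALSE)
  n <- ncol(d)
  if (n == 1L) {
    aa <- abs(d)
  } else {
    h <- numeric(n)
    h[1] <- 1
    if (n %% 2L == 0L) {
      h[n / 2 + 1] <- 1
      h[2:(n / 2)] <- 2
    } else {
      h[2:((n + 1) / 2)] <- 2
    }
    X <- stats::mvfft(t(d)) * h
    aa <- t(Mod(stats::mvfft(X, inverse = TRUE) / n))
  }
  dimnames(aa) <- dimnames(d)
  new("AAMatrix", values = aa, band = band, fs = samplingRate(rec),
      patientId = patientId(rec), seizureId = seizureId(rec),
      annotation = annotation(rec))
}

#' Filter a recording into a band and take its analytic amplitude
#'
#' Convenience wrapper chaining [bandpassFilter()] (skipped for
#' `broadband`) and [analyticAmplitude()].
#'
#' @param rec a [SeizureRecording-class].
#' @param band a [FrequencyBand-class] or band token ([bandByName()]);
#'   `"broadband"` bypasses the filtering stage entirely.
#' @return An [AAMatrix-class].
#' @export
computeAA <- function(rec, band = "broadband") {
  if (is.character(band)) band <- bandByName(band)
  if (!isBroadband(band)) rec <- bandpassFilter(rec, band)
  analyticAmplitude(rec, band = band)
}
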