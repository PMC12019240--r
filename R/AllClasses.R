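#' @import methods
NULL

## Central S4 data objects. In-memory orientation is channels x time
## everywhere; on-disk text matrices are time x channels (long axis row-wise).

#' SeizureAnnotation: seizure window of a recording
#'
#' Marks the annotated seizure onset and offset of a recording, in seconds
#' from recording start, together with the lengths of the pre- and
#' post-seizure windows used for segment summaries (180 s each by default,
#' matching the layout of clinical seizure archives where every record
#' carries three minutes of context on either side of the event).
#'
#' Sample k (0-based) covers time k/fs; windows in seconds are converted to
#' half-open sample ranges with floor(onset*fs) / ceiling(offset*fs).
#' `onset` and `offset` may both be `NA` for unannotated recordings
#' (e.g. oscillator simulations).
#'
#' @slot onset numeric(1), seizure onset in seconds (or NA).
#' @slot offset numeric(1), seizure offset in seconds (or NA).
#' @slot preDuration numeric(1), pre-seizure window length in seconds.
#' @slot postDuration numeric(1), post-seizure window length in seconds.
#' @exportClass SeizureAnnotation
setClass("SeizureAnnotation",
  slots = c(onset = "numeric", offset = "numeric",
            preDuration = "numeric", postDuration = "numeric"),
  prototype = prototype(onset = NA_real_, offset = NA_real_,
                        preDuration = 180, postDuration = 180))

setValidity("SeizureAnnotation", function(object) {
  msg <- character()
  for (s in c("onset", "offset", "preDuration", "postDuration"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("'%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (is.na(object@onset) != is.na(object@offset))
    msg <- c(msg, "'onset' and 'offset' must both be set or both NA")
  if (!is.na(object@onset) && !is.na(object@offset) &&
      (object@onset < 0 || object@onset >= object@offset))
    msg <- c(msg, "need 0 <= onset < offset")
  if (object@preDuration < 0 || object@postDuration < 0)
    msg <- c(msg, "window durations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SeizureAnnotation
#'
#' @param onset,offset seizure window in seconds from recording start.
#' @param preDuration,postDuration pre/post window lengths in seconds
#'   (default 180 each).
#' @return A [SeizureAnnotation-class] object.
#' @examples
#' SeizureAnnotation(180, 240)
#' @export
SeizureAnnotation <- function(onset = NA_real_, offset = NA_real_,
                              preDuration = 180, postDuration = 180) {
  new("SeizureAnnotation", onset = as.numeric(onset),
      offset = as.numeric(offset),
      preDuration = as.numeric(preDuration),
      postDuration = as.numeric(postDuration))
}

#' SeizureRecording: a multichannel recording with seizure annotation
#'
#' Holds a channels x time matrix of real-valued samples (nominally in
#' microvolts), its sampling rate, identifiers, and the seizure annotation.
#' Channel identifiers are the rownames of the data matrix and must be
#' unique. Ingest rejects non-finite samples: NaN is reserved for the
#' downstream padding stage.
#'
#' @slot data numeric matrix, channels x time.
#' @slot fs numeric(1), sampling rate in Hz.
#' @slot patientId,seizureId character(1), opaque identifiers.
#' @slot units character(1), amplitude units (carried, not enforced).
#' @slot annotation a [SeizureAnnotation-class].
#' @exportClass SeizureRecording
setClass("SeizureRecording",
  slots = c(data = "matrix", fs = "numeric",
            patientId = "character", seizureId = "character",
            units = "character", annotation = "SeizureAnnotation"))

setValidity("SeizureRecording", function(object) {
  d <- object@data
  msg <- character()
  if (!is.numeric(d)) msg <- c(msg, "'data' must be a numeric matrix")
  if (nrow(d) < 2L) msg <- c(msg, "need at least 2 channels")
  if (ncol(d) < 1L) msg <- c(msg, "need at least 1 sample")
  if (is.numeric(d) && !all(is.finite(d)))
    msg <- c(msg, "non-finite sample values are not allowed on ingest")
  ids <- rownames(d)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msg <- c(msg, "channel ids (rownames) must be non-empty")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate channel id(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  ann <- object@annotation
  if (length(msg) == 0L && !is.na(ann@onset)) {
    dur <- ncol(d) / object@fs
    if (ann@offset > dur + 1e-9)
      msg <- c(msg, sprintf("annotation offset (%g s) beyond recording end (%g s)",
                            ann@offset, dur))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SeizureRecording
#'
#' @param data numeric matrix, channels x time. Rownames are taken as
#'   channel ids; if absent, `channelIds` must be given.
#' @param fs sampling rate in Hz.
#' @param channelIds optional character vector of channel labels.
#' @param patientId,seizureId identifiers.
#' @param units amplitude units label (default "uV"; informational).
#' @param annotation a [SeizureAnnotation-class], or NULL for unannotated.
#' @return A [SeizureRecording-class] object.
#' @examples
#' x <- matrix(rnorm(4 * 100), 4, 100)
#' rec <- SeizureRecording(x, fs = 100,
#'                         annotation = SeizureAnnotation(0.3, 0.6,
#'                                                        preDuration = 0.3,
#'                                                        postDuration = 0.3))
#' @export
SeizureRecording <- function(data, fs, channelIds = NULL,
                             patientId = "P0", seizureId = "S0",
                             units = "uV", annotation = NULL) {
  data <- as.matrix(data)
  if (!is.null(channelIds)) rownames(data) <- channelIds
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("ch%02d", seq_len(nrow(data)))
  if (is.null(annotation)) annotation <- SeizureAnnotation()
  new("SeizureRecording", data = data, fs = as.numeric(fs),
      patientId = patientId, seizureId = seizureId, units = units,
      annotation = annotation)
}

#' FrequencyBand: a clinical frequency band
#'
#' A named band with low/high cutoff frequencies in Hz. The special band
#' `broadband` has NA cutoffs and means "no filtering applied" (archive
#' signals are already band-limited 0.5--150 Hz at the source).
#'
#' @slot name character(1).
#' @slot lowHz,highHz numeric(1) cutoffs in Hz (NA for broadband).
#' @exportClass FrequencyBand
setClass("FrequencyBand",
  slots = c(name = "character", lowHz = "numeric", highHz = "numeric"))

setValidity("FrequencyBand", function(object) {
  if (is.na(object@lowHz) && is.na(object@highHz)) return(TRUE)
  if (is.na(object@lowHz) || is.na(object@highHz))
    return("cutoffs must both be numbers or both NA (broadband)")
  if (!(object@lowHz > 0 && object@lowHz < object@highHz))
    return("need 0 < lowHz < highHz")
  TRUE
})

#' BinningSpec: fixed-width amplitude binning parameters
#'
#' Parameters of the histogram underlying the entropy: a fixed bin width in
#' amplitude units (default 10), the logarithm base for the entropy
#' (natural, giving nats, or 2, giving bits), and the bin-range mode. With
#' `rangeMode = "timepoint"` (the operational definition and default) the
#' bin edges are re-anchored at the cross-channel minimum at every time
#' point; `"global"` anchors one edge grid at the whole-recording min/max.
#'
#' @slot binWidth numeric(1) > 0, amplitude units.
#' @slot logBase character(1), "natural" or "2".
#' @slot rangeMode character(1), "timepoint" or "global".
#' @exportClass BinningSpec
setClass("BinningSpec",
  slots = c(binWidth = "numeric", logBase = "character",
            rangeMode = "character"),
  prototype = prototype(binWidth = 10, logBase = "natural",
                        rangeMode = "timepoint"))

setValidity("BinningSpec", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || !is.finite(object@binWidth) ||
      object@binWidth <= 0)
    msg <- c(msg, "'binWidth' must be a single positive number")
  if (!object@logBase %in% c("natural", "2"))
    msg <- c(msg, "'logBase' must be \"natural\" or \"2\"")
  if (!object@rangeMode %in% c("timepoint", "global"))
    msg <- c(msg, "'rangeMode' must be \"timepoint\" or \"global\"")
  if (length(msg)) msg else TRUE
})

#' Construct a BinningSpec
#'
#' @param binWidth fixed bin width in amplitude units (default 10).
#' @param logBase "natural" (nats, default) or "2" (bits).
#' @param rangeMode "timepoint" (default) or "global"; see
#'   [BinningSpec-class].
#' @return A [BinningSpec-class] object.
#' @examples
#' BinningSpec()
#' BinningSpec(binWidth = 0.05, logBase = "2")
#' @export
BinningSpec <- function(binWidth = 10, logBase = "natural",
                        rangeMode = "timepoint") {
  new("BinningSpec", binWidth = as.numeric(binWidth),
      logBase = as.character(logBase), rangeMode = as.character(rangeMode))
}

#' AAMatrix: analytic-amplitude (envelope) matrix
#'
#' The per-channel instantaneous analytic amplitude |z(t)| =
#' sqrt(x(t)^2 + H{x(t)}^2) of a (band-filtered) recording; same
#' channels x time shape as its source recording, all entries >= 0.
#'
#' @slot values non-negative numeric matrix, channels x time.
#' @slot band the [FrequencyBand-class] the source was filtered to.
#' @slot fs sampling rate in Hz.
#' @slot patientId,seizureId identifiers carried from the recording.
#' @slot annotation the recording's [SeizureAnnotation-class].
#' @exportClass AAMatrix
setClass("AAMatrix",
  slots = c(values = "matrix", band = "FrequencyBand", fs = "numeric",
            patientId = "character", seizureId = "character",
            annotation = "SeizureAnnotation"))

setValidity("AAMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be numeric")
  if (!all(is.finite(v))) return("analytic amplitudes must be finite")
  if (any(v < 0)) return("analytic amplitudes must be non-negative")
  TRUE
})

#' AESeries: amplitude-entropy time series
#'
#' One entropy value per time sample (nats or bits according to the binning
#' spec), with the band, binning parameters and seizure annotation carried
#' for downstream segmentation. Values are finite and lie in [0, log m];
#' NaN appears only later, in the padded alignment stage.
#'
#' @slot values numeric vector, length = number of samples.
#' @slot band [FrequencyBand-class].
#' @slot binning [BinningSpec-class].
#' @slot fs sampling rate in Hz.
#' @slot patientId,seizureId identifiers.
#' @slot annotation [SeizureAnnotation-class].
#' @exportClass AESeries
setClass("AESeries",
  slots = c(values = "numeric", band = "FrequencyBand",
            binning = "BinningSpec", fs = "numeric",
            patientId = "character", seizureId = "character",
            annotation = "SeizureAnnotation"))

setValidity("AESeries", function(object) {
  if (!all(is.finite(object@values))) return("AE values must be finite")
  if (any(object@values < -1e-12)) return("AE values must be >= 0")
  TRUE
})

#' AlignedAE: NaN-padded seizure x time alignment of AE series
#'
#' Rows are seizures laid out as [pre | ictal | NaN padding | post]: every
#' row shares the common pre length, ictal blocks are padded with NaN up to
#' the longest seizure, and post blocks are aligned after the maximal ictal
#' length so the post average runs over all seizures.
#'
#' @slot values seizures x time numeric matrix with NaN padding.
#' @slot preLen,ictalLen,postLen block lengths in samples (ictalLen is the
#'   maximum across rows).
#' @slot patientIds character, one per row.
#' @slot seizureIds character, one per row.
#' @slot fs sampling rate in Hz.
#' @exportClass AlignedAE
setClass("AlignedAE",
  slots = c(values = "matrix", preLen = "integer", ictalLen = "integer",
            postLen = "integer", patientIds = "character",
            seizureIds = "character", fs = "numeric"))

setValidity("AlignedAE", function(object) {
  v <- object@values
  msg <- character()
  if (object@preLen + object@ictalLen + object@postLen != ncol(v))
    msg <- c(msg, "block lengths do not add up to the number of columns")
  if (length(object@patientIds) != nrow(v))
    msg <- c(msg, "need one patient id per row")
  if (length(msg)) return(msg)
  pre <- seq_len(object@preLen)
  post <- object@preLen + object@ictalLen + seq_len(object@postLen)
  if (object@preLen > 0 && !all(is.finite(v[, pre, drop = FALSE])))
    msg <- c(msg, "pre block must be fully finite")
  if (object@postLen > 0 && !all(is.finite(v[, post, drop = FALSE])))
    msg <- c(msg, "post block must be fully finite")
  if (length(msg)) msg else TRUE
})

#' PMFSnapshot: cross-channel amplitude probability mass at one time point
#'
#' The binned probability mass function of the analytic amplitude across
#' channels at a single time point (or a grand average of such snapshots on
#' a common bin grid). Masses are >= 0 and sum to 1.
#'
#' @slot masses numeric vector of bin probabilities.
#' @slot leftEdges numeric vector of left bin edges (same length).
#' @slot binWidth numeric(1).
#' @slot label character(1), e.g. "T1"/"T2".
#' @slot timeS numeric(1), the snapshot time in seconds (NA for averages).
#' @exportClass PMFSnapshot
setClass("PMFSnapshot",
  slots = c(masses = "numeric", leftEdges = "numeric", binWidth = "numeric",
            label = "character", timeS = "numeric"))

setValidity("PMFSnapshot", function(object) {
  msg <- character()
  if (length(object@masses) != length(object@leftEdges))
    msg <- c(msg, "'masses' and 'leftEdges' lengths differ")
  if (any(object@masses < 0)) msg <- c(msg, "masses must be >= 0")
  if (abs(sum(object@masses) - 1) > 1e-12)
    msg <- c(msg, "masses must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: ground truth of a synthetic recording
#'
#' Generator-side truth enabling recovery tests: the identities of the
#' affected (high-amplitude / incoherent) channels, a per-sample regime
#' label partitioning the time axis, and the full generator parameter set.
#'
#' @slot affected character vector of affected channel ids.
#' @slot regime character vector, one label per time sample.
#' @slot params named list of generator parameters (including the seed).
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(affected = "character", regime = "character", params = "list"))

## show methods ---------------------------------------------------------

setMethod("show", "SeizureAnnotation", function(object) {
  if (is.na(object@onset)) {
    cat("SeizureAnnotation: unannotated\n")
  } else {
    cat(sprintf("SeizureAnnotation: onset %g s, offset %g s (pre %g s, post %g s)\n",
                object@onset, object@offset,
                object@preDuration, object@postDuration))
  }
})

setMethod("show", "SeizureRecording", function(object) {
  cat(sprintf("SeizureRecording '%s/%s': %d channels x %d samples @ %g Hz (%.1f s), units %s\n",
              object@patientId, object@seizureId, nrow(object@data),
              ncol(object@data), object@fs, ncol(object@data) / object@fs,
              object@units))
  show(object@annotation)
})

setMethod("show", "FrequencyBand", function(object) {
  if (is.na(object@lowHz))
    cat(sprintf("FrequencyBand '%s' (no filtering)\n", object@name))
  else
    cat(sprintf("FrequencyBand '%s': %g-%g Hz\n", object@name,
                object@lowHz, object@highHz))
})

setMethod("show", "BinningSpec", function(object) {
  cat(sprintf("BinningSpec: bin width %g, %s log, %s range\n",
              object@binWidth,
              if (object@logBase == "natural") "natural" else "base-2",
              object@rangeMode))
})

setMethod("show", "AAMatrix", function(object) {
  cat(sprintf("AAMatrix [%s]: %d channels x %d samples @ %g Hz\n",
              object@band@name, nrow(object@values), ncol(object@values),
              object@fs))
})

setMethod("show", "AESeries", function(object) {
  cat(sprintf("AESeries [%s] '%s/%s': %d samples @ %g Hz, range [%.3f, %.3f] %s\n",
              object@band@name, object@patientId, object@seizureId,
              length(object@values), object@fs,
              min(object@values), max(object@values),
              if (object@binning@logBase == "natural") "nats" else "bits"))
})

setMethod("show", "AlignedAE", function(object) {
  cat(sprintf("AlignedAE: %d seizures (%d patients) x %d samples (pre %d | ictal <= %d | post %d)\n",
              nrow(object@values), length(unique(object@patientIds)),
              ncol(object@values), object@preLen, object@ictalLen,
              object@postLen))
})

setMethod("show", "PMFSnapshot", function(object) {
  cat(sprintf("PMFSnapshot '%s': %d bins of width %g, mass range [%.3g, %.3g]\n",
              object@label, length(object@masses), object@binWidth,
              min(object@masses), max(object@masses)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d affected channel(s), regimes {%s}\n",
              length(object@affected),
              paste(unique(object@regime), collapse = ", ")))
})
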