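#' Accessors for AmpEntropy objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an AmpEntropy S4 object.
#' @return `samplingRate`, `nChannels`, `nSamples` return single numbers;
#'   `channelIds`, `patientId`, `seizureId` return character vectors;
#'   `annotation` returns a [SeizureAnnotation-class]; `bandOf` a
#'   [FrequencyBand-class]; `recordingData`, `aaValues`, `alignedValues`
#'   numeric matrices; `aeValues` a numeric vector.
#' @name accessors
#' @examples
#' rec <- SeizureRecording(matrix(rnorm(40), 4, 10), fs = 10)
#' samplingRate(rec); nChannels(rec); channelIds(rec)
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))
#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("seizureId", function(x) standardGeneric("seizureId"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("bandOf", function(x) standardGeneric("bandOf"))
#' @rdname accessors
#' @export
setGeneric("aaValues", function(x) standardGeneric("aaValues"))
#' @rdname accessors
#' @export
setGeneric("aeValues", function(x) standardGeneric("aeValues"))
#' @rdname accessors
#' @export
setGeneric("alignedValues", function(x) standardGeneric("alignedValues"))

#' @rdname accessors
setMethod("samplingRate", "SeizureRecording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "AAMatrix", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "AESeries", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "AlignedAE", function(x) x@fs)

#' @rdname accessors
setMethod("channelIds", "SeizureRecording", function(x) rownames(x@data))
#' @rdname accessors
setMethod("channelIds", "AAMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("recordingData", "SeizureRecording", function(x) x@data)

#' @rdname accessors
setMethod("annotation", "SeizureRecording", function(x) x@annotation)
#' @rdname accessors
setMethod("annotation", "AAMatrix", function(x) x@annotation)
#' @rdname accessors
setMethod("annotation", "AESeries", function(x) x@annotation)

#' @rdname accessors
setMethod("patientId", "SeizureRecording", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "AAMatrix", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "AESeries", function(x) x@patientId)
#' @rdname accessors
setMethod("patientId", "AlignedAE", function(x) x@patientIds)

#' @rdname accessors
setMethod("seizureId", "SeizureRecording", function(x) x@seizureId)
#' @rdname accessors
setMethod("seizureId", "AAMatrix", function(x) x@seizureId)
#' @rdname accessors
setMethod("seizureId", "AESeries", function(x) x@seizureId)
#' @rdname accessors
setMethod("seizureId", "AlignedAE", function(x) x@seizureIds)

#' @rdname accessors
setMethod("nChannels", "SeizureRecording", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nChannels", "AAMatrix", function(x) nrow(x@values))

#' @rdname accessors
setMethod("nSamples", "SeizureRecording", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nSamples", "AAMatrix", function(x) ncol(x@values))
#' @rdname accessors
setMethod("nSamples", "AESeries", function(x) length(x@values))

#' @rdname accessors
setMethod("bandOf", "AAMatrix", function(x) x@band)
#' @rdname accessors
setMethod("bandOf", "AESeries", function(x) x@band)

#' @rdname accessors
setMethod("aaValues", "AAMatrix", function(x) x@values)

#' @rdname accessors
setMethod("aeValues", "AESeries", function(x) x@values)

#' @rdname accessors
setMethod("alignedValues", "AlignedAE", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("binningOf", function(x) standardGeneric("binningOf"))
#' @rdname accessors
setMethod("binningOf", "AESeries", function(x) x@binning)

#' @rdname accessors
#' @export
setGeneric("affectedChannels", function(x) standardGeneric("affectedChannels"))
#' @rdname accessors
setMethod("affectedChannels", "SyntheticTruth", function(x) x@affected)

#' @rdname accessors
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))
#' @rdname accessors
setMethod("truthParams", "SyntheticTruth", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("regimeLabels", function(x) standardGeneric("regimeLabels"))
#' @rdname accessors
setMethod("regimeLabels", "SyntheticTruth", function(x) x@regime)
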