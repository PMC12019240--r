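#' Read a recording from a delimited-text matrix plus JSON metadata
#'
#' The matrix file is delimited text whose first row holds the channel ids
#' and whose subsequent rows are time samples (one row per sample; the long
#' time axis streams better row-wise). The separator is taken from the file
#' extension (`.tsv` = tab, anything else = comma). The metadata sidecar is
#' JSON with keys `fs`, `onset_s`, `offset_s`, `patient_id`, `seizure_id`,
#' and optionally `pre_s`, `post_s`, `units`.
#'
#' Annotation windows extending beyond the recording are clipped with a
#' warning. Duplicate or missing channel ids, non-numeric cells (reported
#' with their row/column location), non-finite samples and `onset >= offset`
#' are errors.
#'
#' @param matrixPath path to the delimited matrix file.
#' @param metaPath path to the JSON metadata sidecar.
#' @return A validated [SeizureRecording-class] (annotation embedded).
#' @seealso [writeRecording()] for the inverse; the pair round-trips.
#' @examples
#' rec <- SeizureRecording(matrix(rnorm(40), 4, 10), fs = 512,
#'                         annotation = SeizureAnnotation(0.005, 0.015,
#'                                                        0.005, 0.004))
#' paths <- c(tempfile(fileext = ".csv"), tempfile(fileext = ".json"))
#' writeRecording(rec, paths[1], paths[2])
#' rec2 <- readRecording(paths[1], paths[2])
#' stopifnot(all.equal(recordingData(rec), recordingData(rec2)))
#' @export
readRecording <- function(matrixPath, metaPath) {
  if (!file.exists(matrixPath)) stop("matrix file not found: ", matrixPath,
                                     call. = FALSE)
  if (!file.exists(metaPath)) stop("metadata file not found: ", metaPath,
                                   call. = FALSE)
  sep <- if (grepl("\\.tsv$", matrixPath, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(matrixPath, header = FALSE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE)
  if (nrow(raw) < 2L) stop("matrix file has no sample rows", call. = FALSE)
  ids <- as.character(unlist(raw[1, ], use.names = FALSE))
  if (anyDuplicated(ids))
    stop("format error: duplicate channel id(s) in header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("format error: empty channel id in header", call. = FALSE)
  cells <- as.matrix(raw[-1, , drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !(toupper(cells) %in% c("NA", "NAN")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("parse error: non-numeric cell '%s' at data row %d, column %d",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]),
         call. = FALSE)
  if (any(!is.finite(num)))
    stop("non-finite sample values are not allowed on ingest", call. = FALSE)

  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  for (k in c("fs", "onset_s", "offset_s"))
    if (is.null(meta[[k]])) stop("metadata key '", k, "' missing", call. = FALSE)
  if (meta$onset_s >= meta$offset_s)
    stop("annotation error: onset (", meta$onset_s, ") >= offset (",
         meta$offset_s, ")", call. = FALSE)
  fs <- as.numeric(meta$fs)
  dur <- nrow(num) / fs
  onset <- as.numeric(meta$onset_s)
  offset <- as.numeric(meta$offset_s)
  if (offset > dur) {
    warning(sprintf("annotation offset (%g s) clipped to recording length (%g s)",
                    offset, dur))
    offset <- dur
  }
  if (onset >= offset)
    stop("annotation error: onset at or beyond (clipped) recording end",
         call. = FALSE)
  ann <- SeizureAnnotation(onset, offset,
                           preDuration = meta$pre_s %||% 180,
                           postDuration = meta$post_s %||% 180)
  SeizureRecording(t(num), fs = fs, channelIds = ids,
                   patientId = as.character(meta$patient_id %||% "P0"),
                   seizureId = as.character(meta$seizure_id %||% "S0"),
                   units = as.character(meta$units %||% "uV"),
                   annotation = ann)
}

#' Write a recording to a delimited-text matrix plus JSON metadata
#'
#' Inverse of [readRecording()]: the matrix is written time x channels with
#' a channel-id header, values at full double precision (`%.17g`) so the
#' write/read round trip reproduces the matrix to representation precision.
#'
#' @param rec a [SeizureRecording-class]; must carry a seizure annotation.
#' @param matrixPath,metaPath output paths (`.tsv` extension selects tabs).
#' @return Invisibly, `c(matrixPath, metaPath)`.
#' @export
writeRecording <- function(rec, matrixPath, metaPath) {
  stopifnot(is(rec, "SeizureRecording"))
  ann <- annotation(rec)
  if (is.na(ann@onset))
    stop("annotation error: recording has no seizure annotation", call. = FALSE)
  validObject(rec)
  sep <- if (grepl("\\.tsv$", matrixPath, ignore.case = TRUE)) "\t" else ","
  con <- file(matrixPath, "w")
  on.exit(close(con))
  writeLines(paste(channelIds(rec), collapse = sep), con)
  txt <- apply(t(recordingData(rec)), 1L, function(row)
    paste(sprintf("%.17g", row), collapse = sep))
  writeLines(txt, con)
  jsonlite::write_json(
    list(fs = samplingRate(rec), onset_s = ann@onset, offset_s = ann@offset,
         pre_s = ann@preDuration, post_s = ann@postDuration,
         patient_id = patientId(rec), seizure_id = seizureId(rec),
         units = rec@units),
    metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(matrixPath, metaPath))
}

#' Convert an annotation to half-open sample index ranges
#'
#' Sample k (0-based) covers time k/fs. Seconds convert to 0-based
#' inclusive-exclusive sample ranges via `floor(onset*fs)` /
#' `ceiling(offset*fs)`; the returned indices are 1-based for R subsetting:
#' pre = `[onset - preDuration, onset)`, ictal = `[onset, offset)`,
#' post = `[offset, offset + postDuration)`.
#'
#' @param ann a [SeizureAnnotation-class].
#' @param fs sampling rate in Hz.
#' @param nTotal total number of samples; windows must fit inside.
#' @return A list with integer index vectors `pre`, `ictal`, `post`.
#' @examples
#' segmentIndices(SeizureAnnotation(2, 3, preDuration = 1, postDuration = 1),
#'                fs = 10, nTotal = 40)
#' @export
segmentIndices <- function(ann, fs, nTotal) {
  stopifnot(is(ann, "SeizureAnnotation"))
  if (is.na(ann@onset)) stop("recording is unannotated", call. = FALSE)
  on <- floor(ann@onset * fs)
  off <- ceiling(ann@offset * fs)
  pre0 <- floor((ann@onset - ann@preDuration) * fs)
  post1 <- off + round(ann@postDuration * fs)
  if (pre0 < 0)
    stop("window error: pre window starts before the recording", call. = FALSE)
  if (post1 > nTotal)
    stop(sprintf("window error: post window (to sample %d) exceeds recording length %d",
                 post1, nTotal), call. = FALSE)
  if (on <= pre0 || off <= on || post1 <= off)
    stop("window error: empty segment window", call. = FALSE)
  list(pre = (pre0 + 1L):on, ictal = (on + 1L):off, post = (off + 1L):post1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
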