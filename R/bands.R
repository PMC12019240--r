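#' Clinical frequency bands
#'
#' The canonical clinical EEG band edges used throughout the package:
#' delta 0.5--4, theta 4--8, alpha 8--12, beta 12--35, lgamma (low gamma)
#' 35--80 and hgamma (high gamma) 80--150 Hz, plus `broadband` meaning no
#' filtering.
#'
#' @return `clinicalBands()`: a named list of [FrequencyBand-class]
#'   objects (without broadband). `bandByName()`: a single
#'   [FrequencyBand-class].
#' @examples
#' names(clinicalBands())
#' bandByName("delta")
#' bandByName("6:30")   # custom band, low:high in Hz
#' @export
clinicalBands <- function() {
  edges <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 35), lgamma = c(35, 80), hgamma = c(80, 150))
  lapply(stats::setNames(names(edges), names(edges)), function(nm)
    new("FrequencyBand", name = nm, lowHz = edges[[nm]][1],
        highHz = edges[[nm]][2]))
}

#' @rdname clinicalBands
#' @param name a band token: one of `delta`, `theta`, `alpha`, `beta`,
#'   `lgamma`, `hgamma`, `broadband`, or a custom band as `"low:high"`
#'   (Hz).
#' @export
bandByName <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name == "broadband")
    return(new("FrequencyBand", name = "broadband",
               lowHz = NA_real_, highHz = NA_real_))
  cb <- clinicalBands()
  if (name %in% names(cb)) return(cb[[name]])
  if (grepl("^[0-9.]+:[0-9.]+$", name)) {
    lh <- as.numeric(strsplit(name, ":", fixed = TRUE)[[1]])
    return(new("FrequencyBand", name = name, lowHz = lh[1], highHz = lh[2]))
  }
  stop("unknown band token '", name, "'; use one of ",
       paste(c(names(cb), "broadband"), collapse = ", "),
       " or a custom \"low:high\" band", call. = FALSE)
}

isBroadband <- function(band) is.na(band@lowHz)
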