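#' Zero-phase Butterworth band-pass filtering
#'
#' Filters every channel of a recording into a frequency band with a
#' fourth-order Butterworth band-pass, power response
#' |H(i w)|^2 = 1 / (1 + (w/w_c)^(2n)) with n = 4 at each cutoff, applied
#' forward and backward (zero phase). The two passes square the magnitude
#' response, so the amplitude gain at a cutoff frequency is 0.5 rather than
#' the single-pass 1/sqrt(2); passband tones are passed at unit gain.
#'
#' The filter is realized as a cascade of analytically designed biquad
#' sections (analog prototype poles, frequency prewarping, band-pass
#' transform, bilinear transform per pole pair) rather than one direct-form
#' polynomial: at 512 Hz the delta band's 0.5 Hz cutoff makes the
#' direct-form coefficients numerically ill-conditioned, while each biquad
#' stays well-conditioned. Edge transients are controlled by odd-reflection
#' padding of three periods of the band's low cutoff; the signal must be
#' longer than that padding.
#'
#' @param rec a [SeizureRecording-class].
#' @param band a [FrequencyBand-class] (not broadband) or a band token
#'   accepted by [bandByName()].
#' @param order Butterworth order n (default 4).
#' @return A [SeizureRecording-class] with filtered data (same shape,
#'   ids and annotation).
#' @examples
#' fs <- 512; t <- seq(0, 4 - 1/fs, by = 1/fs)
#' x <- rbind(a = sin(2*pi*20*t), b = cos(2*pi*20*t))
#' rec <- SeizureRecording(x, fs = fs)
#' filt <- bandpassFilter(rec, "beta")
#' @export
bandpassFilter <- function(rec, band, order = 4) {
  stopifnot(is(rec, "SeizureRecording"))
  if (is.character(band)) band <- bandByName(band)
  if (isBroadband(band))
    stop("broadband means no filtering; call analyticAmplitude() directly",
         call. = FALSE)
  fs <- samplingRate(rec)
  if (band@highHz >= fs / 2)
    stop(sprintf("design error: high cutoff %g Hz >= Nyquist %g Hz",
                 band@highHz, fs / 2), call. = FALSE)
  padlen <- filterPadLength(band, fs)
  if (nSamples(rec) <= padlen)
    stop(sprintf("length error: %d samples, need more than %d for stable zero-phase filtering of band %s",
                 nSamples(rec), padlen, band@name), call. = FALSE)
  sos <- butterBandpassSos(band@lowHz, band@highHz, fs, order)
  d <- recordingData(rec)
  out <- t(zeroPhaseSos(t(d), sos = sos, padlen = padlen))
  dimnames(out) <- dimnames(d)
  new("SeizureRecording", data = out, fs = fs, patientId = patientId(rec),
      seizureId = seizureId(rec), units = rec@units,
      annotation = annotation(rec))
}

# reflection padding length: three periods of the low cutoff
filterPadLength <- function(band, fs) as.integer(ceiling(3 * fs / band@lowHz))

# Analytic biquad-cascade design of a digital Butterworth band-pass.
# Analog lowpass prototype poles exp(i*pi*(2k+n-1)/(2n)) -> prewarped
# band-pass transform s -> (s^2 + w0^2)/(B s) -> bilinear transform per
# pole; zeros at z = +/-1 in every section. Gain is normalized to 1 at the
# (prewarped) geometric centre frequency, where the analog response is
# exactly 1, and distributed evenly across sections.
# Returns an ns x 6 matrix, rows (b0, b1, b2, a0, a1, a2).
butterBandpassSos <- function(lowHz, highHz, fs, order = 4) {
  if (order %% 2L != 0L) stop("even filter order required")
  wl <- 2 * fs * tan(pi * lowHz / fs)
  wh <- 2 * fs * tan(pi * highHz / fs)
  w0 <- sqrt(wl * wh)
  B <- wh - wl
  k <- seq_len(order)
  sproto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  sproto <- sproto[Im(sproto) > 0]          # conjugates rebuilt per section
  poles <- unlist(lapply(sproto, function(s) {
    disc <- sqrt((B * s / 2)^2 - w0^2 + 0i)
    c(B * s / 2 + disc, B * s / 2 - disc)
  }))
  zp <- (1 + poles / (2 * fs)) / (1 - poles / (2 * fs))
  sos <- t(vapply(zp, function(p) c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2),
                  numeric(6)))
  wd <- 2 * atan(w0 / (2 * fs))
  z <- exp(1i * wd)
  H <- prod(apply(sos, 1L, function(s)
    (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2)))
  sos[, 1:3] <- sos[, 1:3] * (1 / Mod(H))^(1 / nrow(sos))
  sos
}

# cascade a biquad bank over the columns of a time x channels matrix
# (stats::filter runs each column in C)
applySos <- function(sos, x) {
  n <- nrow(x)
  zero <- matrix(0, 1, ncol(x))
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]
    fir <- b[1] * x + b[2] * rbind(zero, x[-n, , drop = FALSE]) +
      b[3] * rbind(zero, zero, x[-c(n - 1, n), , drop = FALSE])
    x <- matrix(stats::filter(fir, -sos[i, 5:6], method = "recursive"),
                n, ncol(x))
  }
  x
}

# forward-backward (zero-phase) filtering with odd-reflection padding;
# x is time x channels
zeroPhaseSos <- function(x, sos, padlen) {
  x <- as.matrix(x)
  n <- nrow(x)
  padlen <- min(padlen, n - 1L)
  top <- 2 * matrix(x[1, ], padlen, ncol(x), byrow = TRUE) -
    x[(padlen + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], padlen, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - padlen), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- applySos(sos, xp)
  y <- applySos(sos, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[(padlen + 1):(padlen + n), , drop = FALSE]
}
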