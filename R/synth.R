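#' Simulate a Stuart-Landau ring with nonlocal real-part coupling
#'
#' Integrates n Stuart-Landau oscillators on a ring,
#' dz_j/dt = (lambda + i omega - |z_j|^2) z_j +
#'           sigma/(2P) * sum_{k=j-P}^{j+P} (Re z_k - Re z_j),
#' with indices modulo n and a fixed-step RK4 scheme. Coupling through the
#' real parts only is the canonical construction producing amplitude (not
#' phase) chimeras: depending on coupling strength and range the ring
#' settles into a spatially coherent amplitude profile or splits into
#' coexisting coherent and incoherent amplitude subpopulations.
#'
#' The returned recording holds Re z_j(t) as channels at sampling rate
#' 1/dt; the truth labels mark the transient versus post-transient window
#' and carry all parameters. Uncoupled (sigma = 0) each oscillator relaxes
#' to the limit cycle of radius sqrt(lambda); identical initial conditions
#' stay exactly synchronized.
#'
#' @param n number of oscillators (>= 4, even).
#' @param lambda Hopf bifurcation parameter (> 0); limit-cycle radius is
#'   sqrt(lambda).
#' @param omega natural angular frequency.
#' @param sigma coupling strength.
#' @param P coupling range: neighbours per side, 1 <= P <= n/2 - 1.
#' @param dt integration step (dt * omega << 1).
#' @param tMax integration horizon in model time units.
#' @param seed RNG seed (initial-condition perturbations).
#' @param init `"cluster-symmetric"` (two antipodal clusters, the initial
#'   condition from which amplitude chimeras develop) or `"random"`, or
#'   `"identical"` (all oscillators at the same point).
#' @param transientFrac fraction of the run labelled "transient" (default
#'   0.5).
#' @return A list with `recording` (a [SeizureRecording-class],
#'   unannotated) and `truth` (a [SyntheticTruth-class]).
#' @seealso [slPresets()] for the frozen chimera/coherent parameter sets.
#' @export
simulateStuartLandau <- function(n = 64, lambda = 1, omega = 2, sigma = 14,
                                 P = 2, dt = 0.01, tMax = 100, seed = 1,
                                 init = c("cluster-symmetric", "random",
                                          "identical"),
                                 transientFrac = 0.5) {
  init <- match.arg(init)
  stopifnot(n >= 4, n %% 2 == 0, lambda > 0, P >= 1, P <= n / 2 - 1,
            dt > 0, dt * abs(omega) < 0.2, tMax > dt)
  set.seed(seed)
  z <- switch(init,
    "cluster-symmetric" = complex(real = rep(c(1, -1), each = n / 2),
                                  imaginary = rep(c(-1, 1), each = n / 2)) +
      0.01 * complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)),
    "random" = complex(real = stats::runif(n, -1, 1),
                       imaginary = stats::runif(n, -1, 1)),
    "identical" = rep(complex(real = 0.5, imaginary = 0.5), n))
  nsteps <- as.integer(round(tMax / dt))
  kern <- rep(1, 2 * P + 1)
  deriv <- function(z) {
    s <- as.numeric(stats::filter(Re(z), kern, method = "convolution",
                                  sides = 2, circular = TRUE)) - Re(z)
    (lambda + 1i * omega - Mod(z)^2) * z + sigma / (2 * P) * (s - 2 * P * Re(z))
  }
  out <- matrix(0, n, nsteps)
  lim <- 10 * sqrt(lambda)
  for (k in seq_len(nsteps)) {
    k1 <- deriv(z)
    k2 <- deriv(z + dt / 2 * k1)
    k3 <- deriv(z + dt / 2 * k2)
    k4 <- deriv(z + dt * k3)
    z <- z + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(Mod(z))) || any(Mod(z) > lim))
      stop("instability error: |z| exceeded ", lim,
           " at t = ", k * dt, "; try a smaller dt", call. = FALSE)
    out[, k] <- Re(z)
  }
  rownames(out) <- sprintf("osc%03d", seq_len(n))
  rec <- SeizureRecording(out, fs = 1 / dt, units = "model",
                          patientId = "SL", seizureId = sprintf("seed%d", seed))
  regime <- rep(c("transient", "post-transient"),
                c(floor(nsteps * transientFrac),
                  nsteps - floor(nsteps * transientFrac)))
  truth <- new("SyntheticTruth", affected = character(0), regime = regime,
               params = list(n = n, lambda = lambda, omega = omega,
                             sigma = sigma, P = P, dt = dt, tMax = tMax,
                             seed = seed, init = init))
  list(recording = rec, truth = truth)
}

#' Frozen Stuart-Landau parameter presets
#'
#' Two committed parameter sets found by a coupling-strength/range scan
#' and frozen with their initial-condition scheme: `chimera`
#' (sigma = 14, P = 2) develops coexisting coherent and incoherent
#' amplitude subpopulations from the cluster-symmetric initial condition,
#' while `coherent` (sigma = 8, P = 4) collapses to a spatially coherent
#' amplitude profile. Both use n = 64, lambda = 1, omega = 2, dt = 0.01.
#'
#' @return A named list of argument lists for [simulateStuartLandau()].
#' @examples
#' sim <- do.call(simulateStuartLandau, c(slPresets()$coherent,
#'                                        list(tMax = 20)))
#' @export
slPresets <- function() {
  base <- list(n = 64, lambda = 1, omega = 2, dt = 0.01, tMax = 100,
               init = "cluster-symmetric")
  list(chimera = c(base, list(sigma = 14, P = 2)),
       coherent = c(base, list(sigma = 8, P = 4)))
}

#' Simulate a pink-noise seizure surrogate recording
#'
#' A phenomenological surrogate emulating the layout of clinical seizure
#' archives: per channel, independent 1/f-like (pink) noise band-limited
#' to 0.5--150 Hz at a common baseline amplitude scale; during the seizure
#' window [onset, offset) a fixed channel subset ("affected", the
#' spatially localized high-amplitude ictal population) is multiplied by a
#' gain envelope ramping 1 -> gain -> 1 over `rampS` seconds at each end.
#' This reproduces the bimodal cross-channel amplitude distribution -- few
#' very-high-amplitude channels against many low -- whose entropy the
#' pipeline is designed to detect, and gives the generator its recovery
#' guarantee: the broadband AE seizure effect is positive and monotone in
#' the gain.
#'
#' @param m number of channels (>= 2).
#' @param fs sampling rate in Hz (nominally 512).
#' @param preS,ictalS,postS segment durations in seconds (defaults 180,
#'   60, 180; archive seizures range 10--1002 s).
#' @param affectedFraction fraction of channels affected, in (0, 1);
#'   `round(m * affectedFraction)` channels, at least 1 required.
#' @param gain peak ictal gain g >= 1 (g = 1 is the null generator).
#' @param rampS onset/offset ramp length in seconds.
#' @param exponent spectral exponent of the 1/f^exponent noise (default 1).
#' @param baselineAmp per-channel baseline RMS amplitude (default 50,
#'   microvolt scale).
#' @param seed RNG seed; outputs are deterministic given the seed.
#' @return A list with `recording` (annotated [SeizureRecording-class])
#'   and `truth` (a [SyntheticTruth-class]; affected channel ids, regime
#'   label per sample, parameters).
#' @export
simulateSeizureSurrogate <- function(m = 64, fs = 512, preS = 180,
                                     ictalS = 60, postS = 180,
                                     affectedFraction = 0.2, gain = 8,
                                     rampS = 2, exponent = 1,
                                     baselineAmp = 50, seed = 1) {
  stopifnot(m >= 2, fs > 0, preS > 0, ictalS > 0, postS > 0,
            affectedFraction > 0, affectedFraction < 1, gain >= 1,
            rampS >= 0, baselineAmp > 0)
  nAff <- round(m * affectedFraction)
  if (nAff < 1)
    stop("parameter error: affected channel set empty after rounding",
         call. = FALSE)
  set.seed(seed)
  # snap durations to the sample grid so segment windows tile exactly
  preS <- round(preS * fs) / fs
  ictalS <- max(1, round(ictalS * fs)) / fs
  postS <- round(postS * fs) / fs
  Tn <- round((preS + ictalS + postS) * fs)
  ids <- sprintf("ch%03d", seq_len(m))
  affected <- sort(sample(seq_len(m), nAff))

  onset <- preS
  offset <- preS + ictalS
  tIdx <- (seq_len(Tn) - 1) / fs
  ramp <- rep(0, Tn)
  inIct <- tIdx >= onset & tIdx < offset
  if (rampS > 0) {
    up <- pmin(1, pmax(0, (tIdx - onset) / rampS))
    down <- pmin(1, pmax(0, (offset - tIdx) / rampS))
    ramp[inIct] <- pmin(up, down)[inIct]
  } else ramp[inIct] <- 1
  env <- 1 + (gain - 1) * ramp

  x <- matrix(0, m, Tn, dimnames = list(ids, NULL))
  for (c in seq_len(m)) {
    nz <- pinkNoise(Tn, fs, exponent = exponent, lowHz = 0.5, highHz = 150)
    x[c, ] <- baselineAmp * nz
  }
  x[affected, ] <- x[affected, , drop = FALSE] *
    matrix(env, nAff, Tn, byrow = TRUE)

  rec <- SeizureRecording(x, fs = fs,
                          patientId = "SURR", seizureId = sprintf("seed%d", seed),
                          annotation = SeizureAnnotation(onset, offset,
                                                         preDuration = preS,
                                                         postDuration = postS))
  regime <- ifelse(tIdx < onset, "pre", ifelse(tIdx < offset, "ictal", "post"))
  truth <- new("SyntheticTruth", affected = ids[affected], regime = regime,
               params = list(m = m, fs = fs, preS = preS, ictalS = ictalS,
                             postS = postS, affectedFraction = affectedFraction,
                             gain = gain, rampS = rampS, exponent = exponent,
                             baselineAmp = baselineAmp, seed = seed))
  list(recording = rec, truth = truth)
}

# unit-RMS 1/f^exponent noise, band-limited, via spectral shaping of white
# noise (amplitude |X(f)| ~ f^(-exponent/2)). Shaping is done at the next
# highly composite length (fast mixed-radix FFT) and truncated.
pinkNoise <- function(nSamples, fs, exponent = 1, lowHz = 0.5, highHz = 150) {
  n2 <- stats::nextn(nSamples, c(2, 3, 5))
  w <- stats::rnorm(n2)
  X <- stats::fft(w)
  f <- seq(0, n2 - 1) / n2 * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  shape <- numeric(n2)
  ok <- f >= lowHz & f <= min(highHz, fs / 2)
  shape[ok] <- f[ok]^(-exponent / 2)
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n2)[seq_len(nSamples)]
  x / stats::sd(x)
}

#' Generate a reproducible surrogate cohort
#'
#' Draws a cohort of seizure surrogates at archive-like scale: a number of
#' patients each with a drawn number of seizures, ictal lengths drawn
#' uniformly within `ictalRange`, unique patient/seizure ids, everything
#' deterministic given the seed.
#'
#' @param nPatients number of patients.
#' @param seizuresPerPatient length-2 range (min, max) of seizures drawn
#'   per patient.
#' @param ictalRange length-2 range (s) for the drawn seizure durations.
#' @param m,fs,preS,postS,affectedFraction,gain,rampS,baselineAmp passed to
#'   [simulateSeizureSurrogate()].
#' @param seed cohort seed; per-seizure seeds are derived from it.
#' @return A list with one element per seizure, each a list with
#'   `recording` and `truth` (patient ids "P01"..., seizure ids "S01"...).
#' @export
makeCohort <- function(nPatients = 16, seizuresPerPatient = c(2, 5),
                       ictalRange = c(10, 252), m = 64, fs = 512,
                       preS = 180, postS = 180, affectedFraction = 0.2,
                       gain = 8, rampS = 2, baselineAmp = 50, seed = 7) {
  stopifnot(nPatients >= 1, length(seizuresPerPatient) == 2,
            length(ictalRange) == 2, ictalRange[1] > 0,
            ictalRange[1] <= ictalRange[2])
  set.seed(seed)
  vals <- seq(seizuresPerPatient[1], seizuresPerPatient[2])
  counts <- vals[sample.int(length(vals), nPatients, replace = TRUE)]
  # durations snapped to 1/8 s keep sample counts FFT-friendly
  lens <- lapply(counts, function(k)
    pmax(ictalRange[1],
         round(stats::runif(k, ictalRange[1], ictalRange[2]) * 8) / 8))
  seeds <- sample.int(.Machine$integer.max, sum(counts))
  out <- list()
  i <- 0L
  for (p in seq_len(nPatients)) {
    for (s in seq_len(counts[p])) {
      i <- i + 1L
      sim <- simulateSeizureSurrogate(m = m, fs = fs, preS = preS,
                                      ictalS = lens[[p]][s], postS = postS,
                                      affectedFraction = affectedFraction,
                                      gain = gain, rampS = rampS,
                                      baselineAmp = baselineAmp,
                                      seed = seeds[i])
      sim$recording@patientId <- sprintf("P%02d", p)
      sim$recording@seizureId <- sprintf("S%02d", s)
      out[[i]] <- sim
    }
  }
  out
}
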