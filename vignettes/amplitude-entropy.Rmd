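---
title: "Amplitude Entropy: methods and design notes"
author: "AmpEntropy authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amplitude Entropy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmpEntropy)
```

## The measure

Focal seizures typically begin as spatially localized high-amplitude
activity: a small subset of intracranial EEG channels swings to very large
amplitudes while the rest of the electrode network stays near baseline.
Viewed across channels at a fixed instant, the recording then resembles an
*amplitude chimera* — one subpopulation spatially coherent in amplitude,
the other incoherent. AmpEntropy quantifies this cross-channel amplitude
heterogeneity with a single time- and frequency-resolved number.

For each channel $c$ the (optionally band-filtered) signal $x^c(t)$ is
mapped to its analytic amplitude

$$ |z^c(t)| = \sqrt{x^c(t)^2 + \mathrm{H}\{x^c\}(t)^2}, $$

the instantaneous envelope obtained from the Hilbert transform
$\mathrm{H}$. At every sample $t$ the $m$ envelope values are binned into
intervals of fixed width $\Delta_{\text{bin}}$ whose grid is anchored at
the cross-channel minimum, giving occupancies $n_i(t)$ and probabilities
$p_i(t) = n_i(t)/m$, and the **Amplitude Entropy** is the Shannon entropy

$$ \mathrm{AE}(t) = -\sum_i p_i(t)\,\log p_i(t), \qquad 0 \log 0 := 0 . $$

AE is 0 exactly when all channels fall into one bin (a homogeneous
network) and is bounded by $\log\min(m, B)$; a fragmented, long-tailed
amplitude distribution — the chimera-like state — raises it. Because empty
bins contribute nothing, a single far outlier widens the bin range but
barely moves AE; the shift is bounded by
$\log(m{+}1) - \frac{m}{m+1}\log m + \frac{1}{m+1}\log(m{+}1)$, which the
test suite checks against direct recomputation.

## Parameters that matter

* `binWidth` (amplitude units, default 10). The bin width acts as a pure
  scale knob: finer bins raise all AE values, coarser bins lower them, but
  segment contrasts are preserved. The default of 10 suits recordings on
  the microvolt scale where baseline envelopes spread over a few tens of
  µV. For unit-scale signals (e.g. the oscillator simulations below) a
  width of 0.02–0.05 is appropriate. A width larger than the whole
  cross-channel range collapses AE to exactly 0.
* `logBase`: natural log by default (AE in nats); base 2 gives bits and
  only rescales.
* `rangeMode`: `"timepoint"` (default) re-anchors the bin grid at every
  sample's cross-channel minimum — the operational definition of the
  measure. A `"global"` mode anchoring one grid at the recording-wide
  min/max is provided because the verbal definition admits that reading;
  the two differ only when a column's values straddle a global bin edge.
  AE is invariant to channel permutation and to common additive shifts in
  the timepoint mode.
* Frequency bands: delta 0.5–4, theta 4–8, alpha 8–12, beta 12–35, low
  gamma 35–80, high gamma 80–150 Hz, plus `broadband` (no filtering;
  clinical archives are typically already band-limited 0.5–150 Hz).
  Because biological signals follow a $1/f$ spectrum, lower bands carry
  larger amplitudes and hence larger AE values at a fixed bin width; this
  is a known scaling effect, not a bug.

## Numerical choices

**Filtering.** Band-passing uses a fourth-order Butterworth design, power
response $|H(i\omega)|^2 = 1/\{1 + (\omega/\omega_c)^{2n}\}$ with $n = 4$,
applied forward and backward so the net phase shift is zero. Two passes
square the magnitude response: a tone exactly at a cutoff emerges with
amplitude gain $0.5$, not the single-pass $1/\sqrt{2}$ — users comparing
against single-pass filters should expect that factor. The filter is
realized as a cascade of analytically derived biquad sections (prototype
poles, prewarping, band-pass transform, bilinear transform per pole pair)
because the direct-form polynomial for a 0.5 Hz cutoff at 512 Hz is
numerically ill-conditioned — in our measurements a direct-form delta-band
filter built from rooted polynomial coefficients amplified a passband tone
by three orders of magnitude, while every biquad stays well-conditioned.
Edge transients are handled with odd-reflection padding of three periods
of the band's low cutoff, and signals shorter than that padding are
rejected.

**Hilbert transform.** The analytic signal is built with the standard
frequency-domain construction (zero negative frequencies, double positive
ones) over the full recording at once, before any segmentation. No
windowing or trimming is applied at this stage: whether to discard edge
transients is the caller's choice, and the annotated segment windows used
by all downstream statistics exclude the recording edges by construction
(there is always pre/post context around the seizure).

**Time convention.** Sample $k$ (0-based) covers time $k/f_s$. Annotated
windows in seconds become half-open sample ranges via
$\lfloor \text{onset} \cdot f_s \rfloor$ /
$\lceil \text{offset} \cdot f_s \rceil$, so adjacent windows tile without
overlap. Binning places a value equal to the cross-channel maximum into
the last (right-closed) bin, which makes the two-point case
$\{0, 10\}, \Delta = 10$ unambiguous: two bins, one value each.

## Aggregation across seizures and patients

Per-seizure summaries average AE over the pre (default 180 s), ictal, and
post (default 180 s) windows. For grand-average time courses, seizures of
different lengths are aligned as `[pre | ictal | NaN padding | post]`,
padding each ictal block to the longest seizure so post blocks line up and
the post average runs over all seizures. Averaging is two-step: first a
NaN-skipping mean across each patient's seizures, then a plain mean across
patients — each patient contributes equal weight no matter how many
seizures they have (a patient with two identical seizures of AE 1 and
another with one of AE 3 average to 2, never the pooled 5/3). The shaded
uncertainty band is the standard deviation across patient means. An
alternative route resamples (linearly interpolates) every ictal block to a
common length; on constant inputs both routes agree exactly, and both are
exposed (`nanPadAlign` / `timeNormalize`).

## Statistics

Segment differences are tested with a linear mixed-effects model
`meanAe ~ segment + (1 | patient)`, ictal as the reference level, fitted
by maximum likelihood with asymptotic Wald z tests, and a Bonferroni
threshold $\alpha / (3 \times \#\text{bands})$ — 0.05/18 ≈ 0.00278 for the
six-band, three-segment design. The unit of observation is one row per
seizure per segment: this keeps the patient random intercept meaningful at
a 16-patient scale and retains power; a per-patient-averaged variant is
available via `perPatient = TRUE`. A singular fit (zero between-patient
variance) produces a warning, not a failure. Simulation places the Wald
test's size slightly above nominal (≈0.05–0.06 at 16 patients × 6
seizures), the familiar mild liberality of ML-based Wald tests at modest
cluster counts. Post-hoc association tools — Spearman correlation with
midrank ties and $t$-approximate two-sided p, and the Wilcoxon rank-sum
test (exact null for combined $n \le 20$ without ties, otherwise normal
approximation with tie and continuity correction) — are deliberately
uncorrected and labelled exploratory.

## What the synthetic generators emulate

**Seizure surrogate.** Each channel is independent $1/f$ (pink) noise,
band-limited 0.5–150 Hz, at a common baseline RMS of 50 (µV scale). During
the seizure window a fixed random subset (20% of channels by default) is
multiplied by a gain envelope ramping $1 \to g \to 1$ over 2 s at each
end. This reproduces the structural features the measure targets — a
localized high-amplitude subpopulation against a low-amplitude majority,
the archive layout of 3 min pre / variable seizure / 3 min post, and the
$1/f$ spectral character — and guarantees by construction that the
broadband AE seizure effect is positive and monotone in $g$ ($g = 1$ is an
exact null). It does *not* emulate real ictal rhythmicity, spatial
correlation between channels, seizure evolution/propagation, artifacts, or
patient-specific electrode geometry, so passing recovery tests demonstrates
the pipeline's correctness, not clinical performance.

**Oscillator ring.** `simulateStuartLandau` integrates $n$ Stuart–Landau
oscillators with nonlocal coupling through the real parts only,

$$ \dot z_j = (\lambda + i\omega - |z_j|^2) z_j +
   \frac{\sigma}{2P} \sum_{k=j-P}^{j+P} (\mathrm{Re}\,z_k -
   \mathrm{Re}\,z_j), $$

ring indices modulo $n$, fixed-step RK4. This is the canonical
construction for amplitude (not phase) chimeras. Two parameter presets
were fixed by a coupling scan and committed (`slPresets()`): *chimera*
($\sigma = 14$, $P = 2$) develops coexisting coherent and incoherent
amplitude subpopulations from the cluster-symmetric initial condition, and
*coherent* ($\sigma = 8$, $P = 4$) collapses to a spatially homogeneous
amplitude profile; AE separates the two regimes in 10/10 seeds with about
a threefold margin. Integrator checks: uncoupled oscillators relax to the
limit-cycle radius $\sqrt\lambda$; identical initial conditions stay
exactly synchronized (AE $\approx 0$); halving `dt` changes post-transient
envelopes by well under 1% RMS; trajectories exceeding $10\sqrt\lambda$
abort with an instability error.

## Problem sizes used in the checks

The automated checks run the full pipeline on a 16-patient, 64-channel
surrogate cohort with durations scaled to 9 s pre/post and 3–18 s ictal —
the same structure as a clinical archive at a twentieth of the duration,
chosen to keep a complete cohort analysis in the order of minutes on one
core. Mixed-model calibration uses 16 patients × 6 seizures with planted
effect 0.8, intercept SD 0.2 and residual SD 0.1 over hundreds of
replicates; the entropy core is compared element-for-element against a
brute-force loop implementation on 1000 random matrices (up to 64 channels
× 200 samples). Cohort ictal durations are drawn on a 1/8-s grid, which
also keeps FFT lengths highly composite.

## Known limitations

* AE is strictly cross-channel at a fixed time: it carries no information
  about temporal complexity within a channel, and no phase information
  (phase-based chimera indices are out of scope by design).
* The bin width is not adaptive; strongly non-µV-scaled inputs need a
  rescaled `binWidth` to produce informative values.
* Whether to trim filter/Hilbert edge transients before averaging is left
  to the caller; defaults compute segment means only on annotated windows,
  which never touch the recording edges.
* File ingest covers delimited text plus a JSON sidecar. Proprietary
  archive formats should be exported to CSV/TSV externally (for a MATLAB
  `.mat` seizure file: load, transpose to time × channels, `writematrix`,
  and write the `{fs, onset_s, offset_s, patient_id, seizure_id}` sidecar
  by hand); no EDF reader is bundled.
* The mixed model assumes Gaussian residuals of the *segment-mean* AE,
  which is reasonable for window averages but unchecked for very short
  seizures.
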