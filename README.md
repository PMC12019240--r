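# AmpEntropy

Amplitude Entropy (AE) for multichannel neural recordings: a time- and
frequency-resolved measure of how heterogeneous the instantaneous signal
amplitudes are across the channels of a recording.

Focal seizures in intracranial EEG typically start as spatially localized
high-amplitude activity: a few channels swing to very large amplitudes
while the rest of the network stays near baseline — an *amplitude
chimera*-like split into coherent and incoherent subpopulations. AE turns
that split into a single number per time sample and frequency band.
It is intended for researchers analyzing multichannel electrophysiology
(seizure dynamics, network heterogeneity) and for anyone needing a
calibrated, fully synthetic test bed for such pipelines.

## The measure

Each channel's band-filtered signal x(t) is mapped to its analytic
amplitude (Hilbert envelope)

    |z(t)| = sqrt( x(t)^2 + H{x}(t)^2 ).

At every sample t the m cross-channel envelope values are binned at a
fixed width Δ_bin (default 10, µV scale) on a grid anchored at their
minimum, giving probabilities p_i(t) = n_i(t)/m, and

    AE(t) = − Σ_i p_i(t) log p_i(t),   0·log 0 := 0   (nats).

AE is 0 when all channels occupy one bin and grows with amplitude
heterogeneity, bounded by log min(m, B). Filtering uses a zero-phase
fourth-order Butterworth cascade (clinical bands δ 0.5–4, θ 4–8, α 8–12,
β 12–35, lγ 35–80, hγ 80–150 Hz, or `broadband` for none). Variable-length
seizures are aligned by NaN padding, grand averages are two-step (first
across a patient's seizures, then across patients — equal patient
weights), and segment differences are tested with a linear mixed-effects
model (`meanAe ~ segment + (1 | patient)`, ML, Wald z, Bonferroni
α = 0.05/18 for six bands × three comparisons). Synthetic generators — a
pink-noise seizure surrogate and a Stuart–Landau ring with amplitude
chimera regimes — provide ground truth for every stage.

## Worked example

```r
library(AmpEntropy)

sim <- simulateSeizureSurrogate(m = 32, fs = 256, preS = 20, ictalS = 15,
                                postS = 20, affectedFraction = 0.2,
                                gain = 8, seed = 11)
rec <- sim$recording
rec
#> SeizureRecording 'SURR/seed11': 32 channels x 14080 samples @ 256 Hz (55.0 s), units uV
#> SeizureAnnotation: onset 20 s, offset 35 s (pre 20 s, post 20 s)

ae <- computeAE(rec, c("broadband", "beta"))
ae$broadband
#> AESeries [broadband] 'SURR/seed11': 14080 samples @ 256 Hz, range [1.778, 2.913] nats

sm <- rbind(segmentMeans(ae$broadband), segmentMeans(ae$beta))
print(sm, digits = 4)
#>   patientId seizureId      band meanPre meanIctal meanPost
#> 1      SURR    seed11 broadband   2.267     2.564    2.265
#> 2      SURR    seed11      beta   1.543     1.967    1.546

seizureEffect(sm)
#> [1] 0.2975 0.4242
```

During the simulated seizure, 6 of 32 channels carry eight-fold amplitudes;
cross-channel heterogeneity — and hence AE — rises from ≈2.27 to ≈2.56 nats
in the broadband signal (a seizure effect of +0.30 nats, +0.42 in the beta
band), and falls back after offset. Cohort-level helpers (`makeCohort`,
`cohortPipeline`, `segmentEffectReport`) scale this to many patients and
feed the mixed-effects report; `readRecording`/`writeRecording` ingest
your own recordings as CSV/TSV plus a JSON metadata sidecar.

A command-line interface wraps the same functions:

```sh
Rscript inst/scripts/ae.R simulate surrogate --channels 64 --seed 1 --out sim/
Rscript inst/scripts/ae.R compute --matrix sim/matrix.csv --meta sim/meta.json \
        --bands broadband,delta --bin-width 10 --out ae/
```

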