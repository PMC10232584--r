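---
title: "Methods: power, envelope connectivity and cardiac responses under acute stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: power, envelope connectivity and cardiac responses under acute stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`stressfc` re-implements, as a reusable and testable pipeline, a common
analysis pattern in psychophysiological stress research: a within-subject,
two-condition design (neutral vs. negative social-comparative feedback)
analyzed through (i) relative EEG band power with a 1/f spectral
correction, at the sensor level (six frontal electrodes) and for ten
cortical regions of interest, (ii) orthogonalized
amplitude-envelope-correlation (AEC) functional connectivity between those
regions, (iii) event-related cardiac responses expressed as inter-beat
interval (IBI) difference scores, and (iv) a mixed-model statistical layer
with AIC-based family selection, BIC-approximated Bayes factors and
Benjamini-Hochberg FDR control over the full 67-test family. Because raw
EEG of this kind is rarely shareable, the package ships a synthetic-data
generator with known ground truth, so that every estimator can be validated
end to end.

## 1. Spectral analysis

Power spectral densities are Welch estimates: 2-s Hann windows with 50%
overlap (0.5 Hz resolution, at least five windows per 6.2-s epoch),
averaged first across windows and then across epochs, yielding one mean
spectrum per participant, condition and channel/region. The window length
and the aggregation order (epoch-mean spectrum, then one relative power)
are choices of this package; neither materially affects a ratio statistic
but both are fixed for reproducibility.

The 1/f correction multiplies the density by $f^{\gamma}$ with
$\gamma = 1$, flattening the characteristic $1/f$ background of neural
spectra so band ratios are not dominated by the lowest frequencies.
Relative power of band $b = [f_1, f_2]$ is

$$\mathrm{RP}_b = \frac{\int_{f_1}^{f_2} f\,S(f)\,df}{\int_{1}^{40} f\,S(f)\,df},$$

with both numerator and denominator on the corrected spectrum (the
correction could equally be applied only before normalization; correcting
both sides is adopted and stated here because the alternative changes the
numbers). Integrals use the trapezoidal rule on closed band intervals;
trapezoidal integrals are additive across shared edges, so bands that tile
1-40 Hz have fractions summing to exactly 1, and for white noise the alpha
fraction has the closed form $(13^2-8^2)/(40^2-1^2) \approx 0.0657$, which
the test suite checks. Band edges follow the common theta (4-8 Hz), alpha
(8-13 Hz), beta (13-30 Hz) scheme; the sensor-level statistic is the
arithmetic mean of the six frontal channels F7, F3, Fz, FPz, F4, F8.

## 2. Functional connectivity

AEC assumes that functionally coupled regions co-modulate the slow
amplitude envelopes of their band-limited oscillations. The estimator, per
epoch and region pair: band-pass both signals (4th-order zero-phase
Butterworth); orthogonalize pairwise in both orders (least-squares
projection of one real-valued series off the other, removing zero-lag
shared components - the signature of spatial leakage through instantaneous
linear mixing); take Hilbert amplitude envelopes; correlate
$\mathrm{corr}(\mathrm{env}(x), \mathrm{env}(y_{\perp x}))$ and vice
versa; average the two orders (making the statistic exactly symmetric) and
then average over epochs. The first and last 250 ms of each epoch are
discarded before the correlation to avoid filter and Hilbert edge
artifacts, and Pearson correlation is applied to raw (not log) envelopes;
both are package choices where the procedure is otherwise underdetermined.

Two properties define the estimator and are enforced by tests: a single
source mixed linearly into two channels produces a near-unit
*non*-orthogonalized envelope correlation but an AEC near zero (leakage
suppression), and a generator pair with known envelope correlation is
recovered within ±0.1 at 30-60 epochs. A known cost of orthogonalization
is a small negative bias for null pairs when envelopes are smooth (few
effective samples per epoch); it cancels in condition contrasts, which is
what the statistical layer tests.

Regions enter as single time series; composite regions spanning several
atlas scouts are collapsed to their first principal component, with the
sign fixed against the scout mean (or, when scouts cancel in the mean, by
making the dominant loading positive - degenerate but deterministic).
The connection space is all 45 unordered pairs of the 10 regions by 3
bands (135 items), or, anchored on the left/right precuneus, 17 pairs by
2 bands (34 items).

## 3. Cardiac responses

For each feedback event the R-peak closest to the event onset anchors the
IBI series (ties break toward the earlier peak); $\mathrm{IBI}_0$ is the
interval ending at the anchor, with indices running from $-3$ to $+8$.
All intervals are re-referenced to $\mathrm{IBI}_{-2}$, so negative
difference scores mean shorter intervals, i.e. heart-rate acceleration -
the sympathetic signature of an acute stressor. Difference scores can be
negative, so the per-index condition contrast is always fit with the
linear (never the gamma) mixed model. The $-2$ index is identically zero
by construction and its model is degenerate; the pipeline reports it as
such rather than dropping it silently.

## 4. Statistical layer

Every measure is analyzed as `value ~ condition + (1 | participant)` by
maximum likelihood, with two candidate families - linear, and gamma with
identity link whenever all values are positive - and the AIC-minimal fit
selected. The condition contrast is the fixed-effect coefficient of the
two-level condition factor (identical to the estimated-marginal-means
contrast for a balanced two-level factor). The reported t-statistic is the
Wald ratio, but the p-value is a likelihood-ratio test against the
matching null model: in calibration simulations at this design's scale the
Wald standard errors of the gamma GLMM understate the sampling variability
of the contrast by ~15%, inflating the nominal 5% type-I rate to ~15%,
while the LRT is calibrated (~5% on correctly-specified repeated scores).
For the same reason the questionnaire models are fit on the raw repeated
scores, not on participant-by-condition means - collapsing to means leaves
the gamma model mildly misspecified and the LRT slightly anti-conservative
(~7%). Sex is screened as a covariate by a nested-model likelihood
ratio test and retained only at p <= 0.05. Standardized effect sizes scale
the contrast by the model's residual scale - the residual SD for the
linear family, the square root of the dispersion (a coefficient of
variation) for the gamma family - with delta-method CIs that treat the
scale as fixed (the CI method is stated in output because it is a choice,
not a convention). Bayes factors use the BIC approximation
$\mathrm{BF}_{01} = \exp((\mathrm{BIC}_{alt} - \mathrm{BIC}_{null})/2)$,
requiring no priors, and are labelled with the conventional descriptive
bands. FDR control is Benjamini-Hochberg over the enumerated 67-test
family (3 sensor power + 30 source power + 34 connectivity). Participants
enter the EEG analyses only with >= 15 artifact-free epochs in both
conditions.

## 5. The synthetic world

The generator emulates the statistical structure of a 73-participant
within-subject study: 6.2-s feedback-locked epochs at 512 Hz (3174
samples; the sample count is floored so no window reads past the
recording), ~30 epochs per condition, and small condition effects of the
size such studies report.

Each region's signal per band is a constant-modulus sinusoidal carrier
(random in-band frequency and phase per epoch) multiplied by a slow
log-normal envelope: $\mathrm{env} = \exp(\sigma g - \sigma^2)$ with
$g$ a <= 1 Hz Gaussian modulator and $\sigma = 0.5$, normalized so
$E[\mathrm{env}^2] = 1$. Constant-modulus carriers are a deliberate
departure from band-passed-noise carriers: with a stochastic carrier the
analytic-signal envelope is the product of the modulator and the
carrier's own (Rayleigh-distributed) envelope, which attenuates the
realized AEC roughly two-fold below the stored modulator correlation and
would leave the generator without a usable ground truth. With sinusoidal
carriers the Hilbert envelope *is* the modulator, so the stored truth is
exactly what the estimator targets; in-band spectral spread comes from
randomizing the carrier frequency across epochs. Envelope coupling between
regions is induced by shared latent components
($g = \sqrt{\rho}\,c + \sqrt{1-\rho}\,p$ on the Gaussian scale), with the
latent correlation analytically pre-compensated for the attenuation of
exponentiation so the requested value is realized on the envelope scale;
a non-positive-semidefinite request fails fast with the offending pairs
named. Stored coupling truths are epoch-wise mean envelope correlations -
the aggregation level the estimator works at. Modulators are synthesized
on a decimated grid (they carry no energy above 1 Hz) and interpolated.

On top of the oscillations each region receives 1-40 Hz *pink* (1/f)
background activity - pink, not white, so that after the exponent-1
correction the background is flat and the corrected band fractions sit in
a realistic range (alpha ~0.13-0.15) - and channels are formed as
`mixing %*% regions + white sensor noise` through a fixed 16-channel
leadfield-like matrix with full column rank (identity mixing with zero
noise reproduces the regions exactly; the pseudoinverse plays the role of
source reconstruction). Real head-volume conduction, ocular/muscle
artifacts, heteroscedastic sensor noise and genuine 1/f-exponent
variability across participants are *not* emulated, so green tests
establish estimator correctness under the stated model, not robustness to
real-world EEG pathology.

Effect sizes are stated the way the statistics layer reports them.
`band_effects` gives the standardized (gamma-scale) effect of the
relative-power change; the generator converts it to a log-amplitude shift
via the first-order calibration
$\delta = d\,\sigma_{\mathrm{eff}} / p_b$, where
$\sigma_{\mathrm{eff}}^2 = \sigma_{\mathrm{cond}}^2 +
\sigma_{\mathrm{epoch}}^2 / n_{\mathrm{epochs}}$ is the within-participant
residual scale the model will see and $p_b$ the expected baseline band
fraction. The calibration is first-order: Welch estimation noise adds a
further few percent to the realized residual, so recovered effects run
slightly below nominal; the defaults (alpha SES +0.07/+0.11/+0.10 in
left/right precuneus and right PCC, +0.017 envelope-correlation increase
between the precunei, 30 ms IBI shortening at indices 2-7, and negative
valence/arousal shifts on the 9-point scales) reproduce study-scale
t-statistics of roughly 4 for power and are the package defaults rather
than tuned per test. Effect directions are configurable throughout -
including the questionnaire shifts, where the empirical literature itself
is not unanimous about the arousal direction.

Randomness is counter-based: the master seed expands into per-participant,
per-purpose substreams, so any participant subset regenerates
bit-identically - which also lets the pipeline stream participants one at
a time and keep memory flat at full scale.

## 6. Preprocessing boundary and numerics

The package accepts already-cleaned continuous data or epochs: notch
filtering, ICA-based ocular/muscle removal and bad-channel interpolation
are tool-bound manual steps outside its scope. What it does implement:
threshold artifact detection (gradient > 50 uV/ms computed as
$|x_n - x_{n-1}| \cdot f_s/1000$; range > 200 uV per 200 ms; activity
< 0.5 uV per 100 ms; windows slide with 50% overlap - the stride is a
package choice - and any-channel violations flag the sample for all
channels, padded by 200 ms), epoching from -0.2 to +6 s around triggers
with artifact-overlap rejection, average re-referencing, and zero-phase
Butterworth band-passes.

Filtering numerics deserve a note: high-order band-passes with a 1 Hz
edge are unstable in expanded polynomial form, so all filters run as
cascaded second-order sections with steady-state initial conditions and
reflection padding scaled to the slowest pole's decay (validated against
an independent reference implementation to ~1e-14 at matched padding).
The broadband 1-40 Hz filter uses a 10th-order prototype - the two-pass
response attenuates a 45 Hz tone by 23 dB, which a 4th-order design
cannot - while the narrow AEC analysis bands keep a 4th-order design. The
1 Hz edge rings for about a second; epochs are cut after broadband
filtering of the continuous record, so this affects recording edges, not
epoch interiors.

## 7. What the tests do and do not establish

The acceptance suite checks enumeration and bookkeeping exactly
(135/17/34 connections, 67 tests, 73 participants, 3174-sample epochs),
estimator properties against generator oracles (leakage suppression,
envelope-correlation recovery within ±0.1, the white-noise alpha fraction
within ±0.01 of its closed form), statistical calibration on null data at
study scale (type-I error at the 5% level within Monte-Carlo error over
~200 replicates; BH-FDR controlling false discoveries over the 67-test
family), sign-recovery of the injected condition effects across replicate
seeds (scaled down to 24 participants and 10 seeds to fit a CI budget),
and the BF01 closed forms. Simulation-based checks use fixed seeds chosen
before the tests were first run; none of the generator parameters,
thresholds or tolerances were adjusted afterwards. Headline regression
coefficients of any particular empirical study are not reproduction
targets: they depend on raw recordings that are not distributable, and
the package makes no claim about them beyond the structural properties
above.
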