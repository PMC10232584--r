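# stressfc

Analysis pipeline for within-subject psychophysiology experiments that ask
whether an acute psychosocial stressor (negative social-comparative
feedback vs. neutral feedback) changes brain and cardiac activity. It is
aimed at EEG/ECG researchers who want the full measurement chain —
spectral power, envelope-based functional connectivity, event-related
heart-rate responses, and the mixed-model statistics on top — as tested,
scriptable code rather than ad-hoc analysis scripts.

## What it computes

**Relative band power with 1/f correction.** Welch spectra (2-s Hann
windows, 50% overlap) are corrected by multiplying the density with
*f*<sup>1</sup>, and band power is reported as a fraction of the corrected
1–40 Hz total:

> RP<sub>b</sub> = ∫<sub>b</sub> f·S(f) df / ∫<sub>1</sub><sup>40</sup> f·S(f) df,  b ∈ {θ: 4–8, α: 8–13, β: 13–30 Hz}

at the sensor level (mean of F7, F3, Fz, FPz, F4, F8) and for ten cortical
regions of interest (anterior insula, ACC, PCC, precuneus, OFC; left and
right), with composite regions collapsed to their first principal
component across atlas scouts.

**Orthogonalized amplitude envelope correlation (AEC).** Per epoch and
region pair: band-pass, Gram–Schmidt orthogonalization in both orders
(removing zero-lag shared components, i.e. spatial leakage), Hilbert
amplitude envelopes, Pearson correlation, averaged over the two orders and
over epochs. The defining property — a single source mixed into two
channels yields raw envelope correlation ≈ 1 but AEC ≈ 0 — is enforced by
the test suite.

**Event-related cardiac response.** Feedback-locked inter-beat intervals
IBI₋₃…IBI₊₈ (anchor: R-peak closest to the event), re-referenced to
IBI₋₂; negative difference scores = heart-rate acceleration.

**Statistics.** Per measure: `value ~ condition + (1|participant)` fit as
a linear mixed model and (for positive data) a gamma/identity GLMM, the
AIC-minimal family selected; condition contrast with SE, Wald p,
standardized effect size with 95% CI; sex screened by nested-model
comparison; BF₀₁ = exp(ΔBIC/2) Bayes factors; Benjamini–Hochberg FDR over
the 67-test family (3 sensor + 30 source + 34 connectivity tests);
≥15-epoch inclusion rule.

**Synthetic data with ground truth.** A generator emulates the study
world (73 participants, 6.2-s epochs at 512 Hz, log-normal envelopes with
controlled coupling, linear channel mixing, condition-dependent IBI
shortening, gamma-distributed 1–9 questionnaire scores) and stores the
realized relative power and envelope correlations alongside the data, so
every estimator can be scored against known truth. See
`vignettes/methods.Rmd` for the model and every tunable parameter.

## Worked example

```r
library(stressfc)

cfg <- run_config(
  synthetic = simulation_config(n_participants = 8, n_epochs_per_condition = 16,
                                random_seed = 7),
  min_epochs = 15)
res <- run_study(cfg, quiet = TRUE)

nrow(res$stat_table)          # 67  (3 sensor + 30 source + 34 FC tests)
subset(res$stat_table, measure_id == "fc.precuneus_L|precuneus_R.alpha",
       select = c(beta, se, t, p_raw, p_fdr))
#>           beta         se         t     p_raw     p_fdr
#> 50 -0.02606202 0.02492488 -1.045623 0.2957353 0.6498468
res$ibi_contrast[res$ibi_contrast$index == 4, ]
#>   index mean_control mean_negative  estimate       se         t            p
#> 8     4     7.008839     -33.31112 -40.31996 5.000263 -8.063567 4.831139e-07
```

The connectivity row is the left–right precuneus alpha coupling: `beta` is
the condition difference in AEC. The generator injects a +0.017 coupling
increase, but at this toy sample size the AEC sampling noise dominates and
the contrast is a non-significant −0.026 — exactly why the package's
recovery tests run across replicate seeds at larger n (criterion 7 uses 24
participants × 10 seeds). The IBI row says that four beats after negative
feedback the inter-beat interval is ~40 ± 5 ms shorter than after neutral
feedback — heart-rate acceleration consistent with the injected 30 ms
effect at 8 participants.

Every line of `res$report` mirrors the conventional reporting format; the
first line of this run reads

```
- sensor_power.frontal.theta: (ß = -0.008968; SE = 0.0026; t = -3.445;
  p = 0.004051; p_fdr = 0.06581; SES = -0.165; CI = -0.259; -0.0712);
  BF01 = 0.06 (strong evidence for H1) [gamma]
```

(a chance frontal-theta hit at n = 8 that FDR correctly suppresses).

## Command line

```sh
Rscript inst/cli/stressfc.R simulate --config study.yaml --seed 1 --out data/
Rscript inst/cli/stressfc.R run      --config study.yaml --seed 1 --out results/
Rscript inst/cli/stressfc.R report   --out results/
```

`study.yaml` may override any `simulation_config()` field plus
`min_epochs` / `fdr_level`. `run` writes tidy CSVs (stat results, power,
connectivity, IBI tables, epoch counts) and a markdown report.

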