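---
title: "Cuffless blood pressure from a PPG: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cuffless blood pressure from a PPG: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The estimation model

ppgbp estimates mean arterial (MAP), systolic (SBP) and diastolic (DBP)
blood pressure from two quantities that a single finger
photoplethysmogram (PPG) provides beat by beat:

* **heart rate**, HR = 60000 / IBI, with IBI the onset-to-onset
  inter-beat interval in milliseconds, and
* **modified normalized pulse volume**, mNPV = AC / DC — the pulsatile
  (foot-to-peak) amplitude of the PPG divided by its baseline light
  level, an index of finger vascular tone driven by
  alpha-adrenergic sympathetic activity. It is used throughout on the
  natural-log scale.

The physiological rationale is the haemodynamic identity
MAP = CO x TPR (cardiac output times total peripheral resistance),
which becomes additive on the log scale. CO co-varies with HR and TPR
with mNPV, motivating the pooled log-linear calibration

$$\ln BP = a \,\ln HR + b \,\ln mNPV + c$$

fitted separately for each pressure index by ordinary least squares
(`bp_calibrate()`), and applied through the exponential back-transform
$\widehat{BP} = \exp(a \ln HR + b \ln mNPV + c)$ (`predict()`). There
are deliberately **no per-subject terms**: the point of the method is
that one pooled calibration serves unseen readings without an
individual cuff-based calibration procedure. SBP is expected to load
mainly on HR, DBP mainly on ln mNPV, with MAP in between.

Reference MAP is derived from cuff readings with the standard one-third
approximation MAP = DBP + (SBP − DBP)/3 (`map_from_sbp_dbp()`). Because
this formula is linear, the MAP of group means equals the mean of
per-reading MAPs — which is why published group summary statistics can
be checked against it directly.

## From waveform to calibration rows

1. **Conditioning** (`condition_ppg()`): a zero-phase 2nd-order
   Butterworth band-pass, default 0.5–8 Hz, used *only* to locate
   beats. Feature extraction always reads the raw signal, because
   band-passing destroys the DC level that mNPV needs. Cutoffs at or
   above Nyquist are rejected.
2. **Beat detection** (`detect_beats()`): systolic peaks are local
   maxima of the conditioned signal exceeding 30% of the running
   (2-s rolling maximum) amplitude; of two peaks closer than the
   250 ms refractory period (HR ≤ 240 bpm) the higher wins. The beat
   onset is the **pulse foot** — the local minimum nearest before the
   peak — refined on the raw signal within ±30 ms (band-limiting smears
   the foot corner earlier, so the refinement window must cover that
   shift) and interpolated parabolically to sub-sample precision, which
   matters at smartphone frame rates (60 Hz). Ties across a flat
   minimum plateau resolve to the sample nearest the upstroke.
3. **Features** (`beat_features()`): per beat, AC = within-beat maximum
   minus the value at the foot; DC = within-beat mean of the raw
   signal; mNPV = AC/DC. The choice of *per-beat mean* for DC (rather
   than the foot value or a low-pass track) is a documented convention
   of this package; it is stated explicitly so results are
   reproducible. Input polarity must make a pulse a positive
   deflection; `invert = TRUE` accommodates transmittance probes where
   more blood means less light.
4. **Outlier rejection** (`flag_outliers()`): a beat is discarded when
   it is what pushes the standard deviation of the preceding 10-s
   window of accepted beats above 8.0 bpm (HR) or 0.25 a.u. (ln mNPV).
   "Pushes above" is operationalized literally: SD(window + candidate)
   exceeds the limit while SD(window) alone does not. Flagged beats
   leave the window so a single artifact cannot poison the following
   10 s; beats with fewer than two accepted in-window predecessors
   (warm-up) are never flagged; SDs use the n−1 denominator; the rule
   is causal. One beat is one observation, so either criterion removes
   the whole beat.
5. **Block averaging** (`block_average()`): arithmetic means of HR and
   ln mNPV over non-outlier beats in caller-specified 45-s blocks
   (the package does not hard-code an experimental schedule). A block
   is missing when it has no beats or *strictly more than* 20%
   outliers — exactly 20% is still valid.
6. **Calibration and agreement**: valid blocks paired with cuff
   readings feed `bp_calibrate()`; `bp_evaluate()` reports mmHg-scale
   residuals, estimate–residual correlation and a Shapiro–Wilk
   normality check (delegated to `stats::shapiro.test()`).
   Method comparison uses geometric mean regression
   (`gm_regression()`, slope = sign(r)·SD(y)/SD(x), symmetric under
   axis exchange, appropriate when both methods carry error) and
   Bland–Altman analysis (`bland_altman()`, differences = second
   argument minus first). Agreement limits default to **±1 SD** about
   the fixed bias — the convention used in this literature's figures —
   with `limit_multiplier = 1.96` available for conventional limits of
   agreement. Condition contrasts use a paired two-sided t-test and the
   pooled-SD Cohen's d, $d = (\bar b - \bar a)/\sqrt{(SD_a^2 +
   SD_b^2)/2}$; this form is computable from printed group summaries
   alone (`cohens_d()`), which is how the package's checks run without
   raw study data.

`bp_pipeline()` composes all stages and is deterministic for fixed
inputs; the `ppgbp` command-line script exposes each stage and the full
run as subcommands.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `band` | 0.5–8 | Hz | pulse fundamentals 0.5–4 Hz plus low harmonics; rejects drift and mains |
| `refractory_s` | 0.25 | s | caps HR at 240 bpm, above any plausible finger pulse |
| `prominence` | 0.3 | fraction | rejects dicrotic bumps and noise peaks without missing weak pulses |
| `window_s` | 10 | s | reference window of the outlier rule |
| `hr_sd_limit` | 8.0 | bpm | acceptance SD limit for HR |
| `lnmnpv_sd_limit` | 0.25 | a.u. | acceptance SD limit for ln mNPV |
| `block_len_s` | 45 | s | one quarter of a 3-min condition period |
| `max_outlier_frac` | 0.20 | fraction | strict "over 20%" missing rule |
| `limit_multiplier` | 1 | SD | ±1 SD agreement band (1.96 optional) |

## What the simulators emulate

`simulate_ppg()` builds each beat from an asymmetric kernel
$w(u) \propto u^2 (1-u)^4$ (fast systolic upstroke, peak at one third
of the beat, slow diastolic decay), scaled to the AC profile and
mean-centred on the DC profile so that the extractor's definitions (AC
= foot-to-peak, DC = within-beat mean) recover the generating values
exactly up to discretization. Only foot timing, amplitude and baseline
are contractual — the kernel shape is a free modelling choice, since
those three are all the downstream quantities read. Gaussian sample
noise, baseline drift (a DC profile), 20-ms artifact transients and
both smartphone-like (60 Hz) and laboratory-like (1 kHz) rates are
supported. Ground truth (onsets, IBIs, AC, DC per beat) travels with
the record (`pulse_truth()`).

`simulate_cohort()` draws per-subject, per-condition, per-block
(HR, ln mNPV) pairs and generates reference SBP and DBP from the
log-linear model with homoscedastic Gaussian residuals on the ln scale;
MAP is then *derived* with the one-third formula, exactly as a cuff
study would produce it. Defaults emulate a rest/mental-stress protocol:
13 subjects × 2 conditions × 2 blocks, typical HR 75 vs 92 bpm,
ln mNPV −3.63 vs −4.37, between-subject/between-block SDs chosen so the
marginal spreads match those magnitudes (e.g. ln HR SD
$\sqrt{0.16^2 + 0.10^2} \approx 0.19$, matching a ~14-bpm SD at
75 bpm).

Choices worth knowing about:

* **Condition means are interpreted on the log scale** (ln 75, ln 92).
  At coefficients of variation near 0.2 the gap to arithmetic means is
  under 2% and immaterial to every check in the package.
* **SBP/DBP residuals are correlated (r = 0.7)** — both come from the
  same cuff reading — and the rare draw that would cross SBP below DBP
  is redrawn (rejection fraction ~1e−4 at defaults; parameters whose
  mean structure crosses are rejected with an error). Physiological
  readings always satisfy SBP > DBP, and a generator for them must
  respect that support.
* **`map_mode`**: the default `"derived"` mirrors the measurement
  process, but then ln MAP is not *exactly* log-linear in the
  predictors, so machine-precision identifiability checks of the MAP
  fit are impossible by construction. `map_mode = "model"` generates
  MAP from its own coefficients for exactly that purpose (at the cost
  of no longer bracketing MAP between DBP and SBP in rare draws).
* **`residual_sd` defaults to 0.09** on the ln-BP scale. This is the
  noise level at which the pooled fit attains a multiple correlation
  near 0.7 at the default predictor spread — the accuracy regime the
  method is designed for. `calibrate_residual_sd()` recomputes the
  value for any target R by measuring the noiseless predictor variance
  on a large cohort and solving $R^2 = V/(V + \sigma^2)$.
* **Blocks within a condition are independent**; no within-block
  autocorrelation is modelled, since everything downstream consumes
  45-s averages.

What the simulators do **not** emulate: light-transport physics and
wavelength-dependent penetration depth (the systematic offset between
green-light smartphone and near-infrared laboratory mNPV), pulse-wave
morphology (dicrotic notch), motion artifacts with realistic spectra,
respiratory modulation, or within-subject correlation structure beyond
a random intercept. Passing tests on synthetic data therefore
demonstrate the *correctness of the algorithms under their stated
assumptions*, not field accuracy on real smartphone recordings.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses reflection padding (3 periods of the low
  cutoff) so start-up transients stay outside the record.
* Sub-sample onset timing comes from parabolic interpolation through
  the three samples around the raw-signal minimum; at a corner-like
  foot the offset is clamped to ±0.5 sample.
* A flat signal yields "no beats found"; a record shorter than two
  refractory periods "signal too short"; non-positive within-beat DC
  (wrongly offset or inverted input) "non-positive DC level". A
  zero-amplitude beat is emitted with mNPV 0 and undefined ln mNPV
  rather than dropped.
* `hr_bpm = 60000 / ibi_ms` is computed, never stored independently,
  so the identity holds to the last bit; the simulator keeps generated
  IBIs rather than re-differencing accumulated onset times for the
  same reason.
* Rank-deficient calibration designs error as "degenerate design";
  fewer than 4 complete rows as "insufficient data". Zero-variance
  inputs to the agreement statistics error ("degenerate input") or
  return `NA` where a statistic is undefined (paired t on constant
  differences).
* Fits with residual variance below 1e−12 report estimate–residual
  correlation and normality checks as `NA` (not applicable) instead of
  dividing by ~0.

## Problem sizes used in the checks

The package's own test suite and acceptance script run entirely on
synthetic data at sizes chosen to make every stochastic check stable:
1000 random beat series of 40 beats for the outlier-rule oracle, 1000
Monte-Carlo replicates of n = 49 calibrations for unbiasedness (3
standard-error bands), a 9-minute 60-Hz recording with 12 blocks for
the closed-loop run, and 10⁴ subjects for law-of-large-numbers checks
of the cohort marginals.

## Known limitations

* The per-beat-mean DC convention is one defensible reading of AC/DC;
  a device whose firmware uses a low-pass DC track will produce offset
  (but strongly correlated) ln mNPV values.
* The pooled-SD Cohen's d reproduces published MAP/DBP effect sizes
  from summary statistics exactly, but a paired-design d (correcting
  for the within-pair correlation) would differ slightly; the package
  does not guess which correction any given study used.
* Geometric mean regression needs non-degenerate variance in both
  inputs and at least 3 pairs; it is reported with r so users can judge
  when the slope is meaningful.
* Calibration transfer across devices (e.g. green-light smartphone to
  infrared laboratory PPG) is out of scope: fit each device's own rows.

```{r example}
calib <- simulate_cohort(seed = 1)
fit <- bp_calibrate(calib)
glance(fit)
```
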