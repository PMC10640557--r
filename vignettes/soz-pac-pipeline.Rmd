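---
title: "Mapping seizure-onset-zone electrodes from interictal phase-amplitude coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping seizure-onset-zone electrodes from interictal phase-amplitude coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In drug-resistant focal epilepsy, resective surgery depends on localizing
the seizure onset zone (SOZ) -- the cortical territory where seizures
start. Clinicians label intracranial (ECoG) electrodes as SOZ or NSOZ by
visually reviewing long recordings, which is slow and error-prone.
Interictal (between-seizure) recordings contain a usable signature:
within the SOZ, the amplitude of high-frequency oscillations (HFOs;
ripples 80--260 Hz and fast ripples 260--560 Hz) is modulated by the phase
of slow rhythms (0.5--24 Hz). `sozpac` turns that signature into a
quantitative pipeline: narrow-band phase-amplitude coupling (PAC) features
per electrode and per 20-s segment, group statistics between SOZ and NSOZ
electrodes, and imbalance-aware classifiers evaluated by a chronological
nested cross-validation.

## The coupling statistic

Each channel is band-pass filtered into 16 phase bands tiling 0.5--24 Hz
(bandwidths 0.5, 1 and 2 Hz below 1, 8 and 24 Hz respectively) and 16
amplitude bands tiling 80--560 Hz in 30-Hz steps. Instantaneous phase
$\phi(t)$ and amplitude $A(t)$ come from the Hilbert transform, and each
series is cut into non-overlapping 20-s segments (one hour gives 180).
For a band pair, the raw mean-vector-length modulation index is

$$ MI_{raw} = \left| \frac{1}{N}\sum_t A(t)\, e^{i\phi(t)} \right| , $$

the modulus of the mean complex vector that points amplitude mass at its
concurrent phase. Because $MI_{raw}$ scales with amplitude, it is z-scored
against a surrogate ensemble: the phase series is circularly rotated by a
random shift (uniform on $[s_{min}, N - s_{min}]$ samples,
$s_{min}$ = 1 s by default), the index recomputed 100 times, and

$$ MI = (MI_{raw} - \mu_{surr}) / \sigma_{surr}. $$

Under no coupling $MI$ is approximately standard normal (the test suite
verifies $|\bar{MI}| < 0.1$, $sd \in (0.8, 1.2)$ over 200 null segments),
and it is exactly invariant under global amplitude rescaling. The 16
$\times$ 16 matrix of z-scored indices per channel-segment is the
comodulogram (phase frequency on x, amplitude frequency on y).

Implementation note: for a shift $s$, $\sum_t A(t)e^{i\phi(t+s)}$ is a
circular cross-correlation, so the index for *every* shift is obtained
with three FFTs; surrogates then just sample 100 entries. Surrogate draws
are seeded per (channel, segment, cell), so results are reproducible and
independent of evaluation order. Negative z values are retained.

## Filtering choices

Filters are Kaiser-window FIRs designed for 60 dB or more stopband
attenuation, applied by FFT convolution with the (integer) group delay
removed -- exactly zero-phase for an odd-length linear-phase FIR, which
matters because lagged phase estimates would bias the coupling. The tap
count follows the Kaiser formula with the transition width set to *half
the band's width*, clamped to odd values in [101, 20001]. The
half-bandwidth rule guarantees a band-centred tone reaches full passband
gain even in 1-Hz-wide bands (a fixed-cycles rule would leave the
transition wider than the band itself and attenuate in-band content).
The lowest phase band (0.5--1 Hz) hits the 20001-tap cap and retains a
mild passband droop; at 2000 Hz that cap corresponds to 10 s of signal,
so recordings must comfortably exceed the filter length. Record edges are
retained (not trimmed), so exactly 180 segments come out of one hour;
edge segments see filter roll-in. No notch filtering, re-referencing, or
artifact rejection is applied.

## The synthetic generator

Patient ECoG is not distributable, so every stage is exercised on
synthetic multichannel recordings. SOZ channels carry injected coupling:

$$ x(t) = s(t) + \tfrac{1}{2}\bigl(1 + \kappa \cos\phi_s(t)\bigr)
  \sin(2\pi f_a t) + \varepsilon(t), $$

where $s(t)$ is a *stochastic narrowband* slow rhythm (Gaussian process
with a Gaussian spectral window of 1 Hz FWHM centred at $f_p$, power
matched to a unit sinusoid), $\phi_s$ its Hilbert phase, $\kappa \in
[0,1]$ the coupling depth (0 for NSOZ channels), and $\varepsilon$ white
Gaussian noise (sd 0.5 by default; an optional 1/f background and
spike-like transients are off by default). Defaults follow the clinical
regime the pipeline targets: 2000 Hz sampling, one hour, SOZ:NSOZ
imbalance in the observed 1:3.75--1:19 range of the reference cohort
(`fcd_cohort()`).

The slow rhythm is stochastic *on purpose*. For a deterministic sinusoid,
$\phi(t+s) = \phi(t) + \omega s$, so a circular shift merely rotates the
mean vector and leaves $MI_{raw}$ unchanged: the surrogate distribution
collapses ($\sigma_{surr} \to 0$) and the z-score is undefined no matter
how strong the coupling. Cortical slow waves have diffusing phase, which
is precisely what makes time-shift surrogates a valid null; the generator
reproduces that property. The code guards the truly degenerate case
(constant surrogate spread) by returning 0 with a warning. What the
generator does *not* emulate: 1/f broadband structure (optional flag
only), spatial correlation between channels, non-stationarity over the
hour, pathology-specific waveform shapes. Passing tests therefore show
correct recovery of injected narrow-band coupling under white noise, not
clinical performance.

Per-channel signals draw from independent deterministic substreams of the
seed, so adding channels never alters earlier ones, and depth $\kappa$
maps monotonically onto the recovered z-scored index (tested over
$\kappa \in \{0, 0.25, 0.5, 1\}$).

## Electrode statistics

Each electrode's comodulogram is averaged over time, and eight named band
pairs are extracted as unweighted means over whole grid-cell blocks:
$\delta$ (0.5--4), $\theta$ (4--8), $\alpha$ (8--12), $\beta$ (12--24 Hz)
crossed with ripple (80--260) and fast ripple (260--560 Hz). ($\theta$ is
taken as 4--8 Hz; the 4--7 Hz convention seen elsewhere does not align
with the grid's cell edges.) SOZ and NSOZ electrode values are compared
per band pair with a two-sided Mann-Whitney U test at $\alpha = 0.001$,
with no correction across the eight pairs (mirrored from the source
analysis; a Bonferroni reader can divide by 8). The p value is exact --
full enumeration of group assignments, ties handled exactly -- whenever
$\binom{n_1+n_2}{n_1} \le 10^5$, e.g. 4 SOZ vs 16 NSOZ electrodes, and a
tie-corrected normal approximation with continuity correction otherwise.
Exactness matters at strict thresholds: a 4-vs-16 cohort cannot reach
$p < 0.001$ under the normal approximation even at complete separation,
while the exact p at complete separation is $2/\binom{20}{4} \approx
4.1\times 10^{-4}$.

## Classifiers and imbalance handling

Segment-level comodulograms (flattened to 256 features for the vector
models) are classified as SOZ/NSOZ by five models:

- **SVM, linear and RBF kernels** (`e1071`), with per-class penalties
  $C_i = C\,\omega_i$, $\omega_i = N/(2 N_i)$ -- inverse-frequency
  weights satisfying $\sum_i n_i \omega_i = N$. Features are standardized
  with training-split statistics only. For ranking (AUC) the decision
  value is used; Platt-calibrated probabilities are fitted for the final
  per-electrode report (Platt scaling is monotone, so AUC is identical).
  C and gamma grids are conventional log ranges (`default_grid()`),
  overridable; `gamma = NA` means the scale heuristic
  $1/(p \cdot \overline{var})$.
- **Gradient-boosted trees** via `xgboost` with leaf-wise growth
  (`tree_method = "hist"`, `grow_policy = "lossguide"`), tuned over
  `num_leaves` {35..65}, `max_depth` {4,6,8,10}, `learning_rate`
  {0.01,0.05,0.1,0.15}, `min_data_in_leaf` {20,40,60,100} (448
  configurations); positives weighted by $n_-/n_+$.
- **A 2-D CNN** on the 16 $\times$ 16 comodulogram, implemented in
  package R code on BLAS matrix operations: conv(32, 3$\times$3) and
  conv(64, 3$\times$3) each followed by batch normalization, 2$\times$2
  max-pool; conv(128, 3$\times$3) + batch norm + max-pool; dense(128,
  ReLU) with 0.5 dropout; sigmoid output. ReLU activations and He-uniform
  initialization in the conv layers ('same' padding; batch normalization
  placed after the activation, the Keras idiom when the activation lives
  in the conv layer). Adam (lr $10^{-3}$), 100 epochs, batch 128, early
  stopping with patience 10 on validation loss, best weights restored.
  Trained with either the **focal loss**
  $-\alpha_t (1-p_t)^\gamma \log p_t$ or the **class-balanced focal
  loss** $-(1/E_n)(1-p_t)^\gamma \log p_t$ with effective number
  $E_n = (1-\beta^n)/(1-\beta)$, $n$ the sample's class count in the
  current training subset. (The class-balanced loss is implemented with
  the leading minus sign so it is a non-negative loss; a sign-free
  reading would reward misclassification.) Natural logarithms throughout;
  probabilities clamped to $[10^{-7}, 1-10^{-7}]$. Gradients are verified
  against finite differences in the test suite.

## Chronological nested cross-validation

Comodulograms drift over time, so folds are chronological: the segment
timeline is cut into $K+1$ equal folds ($K = 5$), identically across
electrodes. Split $k$ trains on folds $1..k$ and tests on fold $k+1$;
every test segment is strictly later than every training segment. The
inner loop is a single chronological 80/20 split of the training set
(first 80% = training subset, last 20% = validation): grid search selects
the configuration maximizing validation AUC (ties broken by grid order),
the model is refit on the full training set (the CNNs keep the validation
split for early stopping), and test AUC is recorded. The summary is the
mean $\pm$ sd over the $K$ splits; a split whose validation or test fold
degenerates to one class yields NA and is excluded with a warning.
Segments -- not electrodes -- are the classification unit; electrode-level
SOZ scores are the mean test-segment probability per split, averaged over
splits, so each split contributes equally.

## Problem sizes used by tests and the acceptance script

Chosen once as realistic desk-scale conditions: null calibration uses 200
independent 20-s segments at 250 Hz with 100 surrogates on one band pair;
parameter recovery uses 4 SOZ + 16 NSOZ electrodes, 5-min recordings at
1200 Hz, 50 surrogates; the end-to-end classification benchmark uses
1 SOZ + 9 NSOZ electrodes (the 1:9 imbalance regime), 12-min recordings
at 1200 Hz (36 segments, 6 folds), $\kappa = 0.8$, and an RBF SVM with a
small C/gamma grid. 1200 Hz keeps the full amplitude grid below Nyquist
while bounding cost; the generator default remains 2000 Hz.

## Known limitations

- The generator is a narrow-band caricature of ECoG; claims transfer to
  clinical data only qualitatively.
- Only the MVL modulation index is implemented (no Tort KL-MI or
  GLM-PAC), and surrogate z-scoring is the only bias correction.
- The CNN engine is single-threaded R; it is adequate for
  comodulogram-sized inputs but not a general deep-learning tool.
- Per-split standard deviations are over the $K$ splits; no bootstrap.

## A worked run

```{r example}
library(sozpac)

cfg <- synth_config(fs = 1200, duration = 720, n_soz = 1, n_nsoz = 9,
                    kappa = 0.8, seed = 101)
rec <- generate_recording(cfg)
ten <- compute_comodulograms(rec, spec = surrogate_spec(100, seed = 11))
autoplot(ten)

tab <- electrode_band_pairs(ten)
soz_band_tests(tab)

feat <- as_feature_matrix(ten)
plan <- plan_splits(36, n_electrodes = 10, K = 5)
cv <- run_nested_cv(feat, "svm_rbf", plan,
                    grid = tidyr::expand_grid(C = c(1, 10),
                                              gamma = c(NA, 0.01)))
glance(cv)
autoplot(cv)
```
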