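---
title: "Methods: interbrain coupling analysis for dual-EEG hyperscanning"
author: "dyadsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interbrain coupling analysis for dual-EEG hyperscanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The problem

Hyperscanning experiments record EEG simultaneously from two interacting
subjects — here a human and a dog, each wearing a 16-channel montage covering
frontal, parietal, temporal and occipital regions at 500 Hz — and ask whether
and how their neural activity couples during social interaction. `dyadsync`
implements the full analysis chain for such paired recordings:

1. **Preprocessing** — low-pass filtering, detrending, artifact detection
   (amplitude rule plus a wavelet-feature neural-network classifier), and
   excision of flagged 1-s windows with the trace ends joined.
2. **Spectral analysis** — 1-s non-overlapping multitaper power spectra at
   integer frequencies 4–30 Hz, peak-normalized per frequency, averaged into
   one band-power series per region per subject at 1 sample/s.
3. **Interbrain correlation** — Pearson correlation between the two
   subjects' region power series, for all 16 region pairs, validated against
   a cross-session pseudo-pair null.
4. **Directionality** — a bivariate MVAR model on the paired region series
   and generalized partial directed coherence (GPDC) in both directions,
   quantifying leader–follower asymmetry.
5. **Attention** — theta/beta ratios (TBR) per region, normalized to a
   no-interaction baseline.
6. **Group statistics** — Friedman tests across days, Mann–Whitney U
   (exact for small samples), Holm–Šídák adjustment, OLS regression of
   coupling on social exposure, and a logistic growth fit with a plateau-day
   estimate.

Because no public dual-EEG data accompany this problem, the package ships a
**synthetic dyad simulator** whose ground truth (coupling strength,
direction, lag, artifact masks) drives every validation test.

## The signal model of the simulator

Each region of each subject carries a latent log-envelope $z(t)$, a
unit-variance AR(1) process with time constant 1.5 s. The observable channel
signal is

$$x_c(t) = A_0\, g_c\, e^{\sigma z_r(t) - \sigma^2} \cdot u_c(t) + p_c(t) + \varepsilon_c(t),$$

with $u_c$ an independent band-limited (4–30 Hz) Gaussian carrier per
channel, $p_c$ 1/f background noise, $\varepsilon_c$ white sensor noise,
$\sigma = 0.6$, channel gains $g_c \sim U(0.8, 1.25)$, and $A_0$ chosen so
the rhythmic component dominates (about 17 µV rms, roughly 95% of
broadband power inside 4–30 Hz versus above 40 Hz — the spectral-realism
property the tests check). The exponential keeps envelopes positive;
$E[e^{2\sigma z - 2\sigma^2}] = 1$ normalizes mean power.

**Coupling** between the two subjects in a region pair is implemented in the
latent domain with variance-preserving mixing:

$$z_{\text{follower}}(t) = s\, z_{\text{leader}}(t - \ell) + \sqrt{1 - s^2}\, z_{\text{own}}(t),$$

so that the latent envelope correlation equals the strength $s \in [0,1]$
exactly and the leader precedes the follower by $\ell$ samples. This makes
the strength axis interpretable (correlation on the latent scale), keeps
day-schedule shapes undistorted when mapped through the measurement chain,
and satisfies independence at $s = 0$ and near-perfect coupling at $s = 1$
by construction. Day schedules multiply $s$; `logisticSchedule()` provides a
saturating familiarity curve whose 95% point falls near day 7 with the
defaults.

**What the simulator does not emulate**: volume conduction, realistic
inter-channel covariance, biophysical forward models, species-specific
amplitude distributions (unknown for dog EEG), or behavioral covariates.
Passing tests therefore demonstrate that the *pipeline recovers what the
generator encodes* — strength, monotonicity, direction, day trends — not
that it would recover the same quantities from any real recording.

**Artifacts** of the five standard classes are injected additively inside
event supports only: ocular (blink-shaped low-frequency deflections,
positive lobe then negative trough, on frontal channels), EMG (band-limited
noise above 30 Hz), cardiac (1–2 Hz biphasic spike trains), mains
interference (pure 50 or 60 Hz sinusoid), and electrode faults (step, flat,
or high-variance segments on a single channel). The exact sample mask is
returned as ground truth.

All randomness flows from one integer seed through a 31-bit mixing function
(`childSeed`), so sessions, studies and training sets are bit-reproducible
and independently addressable.

## Preprocessing choices

* **Low-pass filter.** The nominal specification — a 10th-order Butterworth
  at 250 Hz applied to 500 Hz data — places the cutoff exactly at Nyquist,
  where an IIR realization is numerically meaningless. The filter is
  implemented as the *analytic squared Butterworth magnitude response*
  (the forward–backward, zero-phase convention) applied in the frequency
  domain with reflection padding: exact DC gain 1, no stability issues at
  any cutoff. The default cutoff is 245 Hz; 250 Hz is permitted with a
  warning. Since all downstream analysis is power-based in 4–30 Hz, the
  choice is inconsequential and phase handling is moot.
* **Amplitude rule.** Any 1-s window containing a sample exceeding 300 µV
  in magnitude (strictly) on any analysis channel is flagged. The boundary
  convention (strict `>`) is arbitrary and documented.
* **ANN detector.** Each channel-window is summarized by Daubechies-4
  wavelet relative energies (5 levels, periodic pyramid on the zero-padded
  segment), log variance, excess kurtosis, log peak amplitude, mains-band
  power share, sub-4 Hz share, above-30 Hz share, and a zero-energy flag
  (defined fallback for flat segments). A single-hidden-layer network
  (32 units, softmax, weight decay $10^{-3}$) is trained on balanced
  synthetic segments. A window is flagged when **three or more channels**
  exceed posterior 0.5, or when a **single channel** both exceeds posterior
  0.9995 *and* is a variance outlier against that channel's own per-window
  spread (window SD above 4× or below 1/16 of the channel median). The
  multi-channel consensus controls the false-alarm inflation that a plain
  16-channel union suffers (at a per-channel false-positive rate $f$, a
  union flags $1 - (1-f)^{16}$ of clean windows), and remains sensitive
  because every multi-channel artifact class drives at least four channels;
  the conjunctive single-channel branch catches one-channel electrode
  faults — flat, step and noisy segments are variance-extreme — without
  inheriting the posterior-tail noise that varies between training runs.
  Training segments draw their 1/f background from a 30-s trace so they
  carry the same sub-hertz drift as windows cut from a long recording.
* **Joint excision.** Flags are unioned across the two subjects of a dyad
  and whole windows are excised from both traces, keeping the paired series
  aligned sample-for-sample; gaps are closed by joining, never interpolated.
  Reported `fractionRemoved` is relative to the windowed timeline.

## Spectral estimation

Power spectra use the multitaper method: 7 DPSS tapers at time
half-bandwidth product NW = 4 (the standard $2\,\mathrm{NW} - 1$ taper
count), 1-s windows without overlap, integer bins 4–30 Hz (27 bins; the
1-s window makes the bin spacing exactly 1 Hz). Tapers come from the
symmetric tridiagonal eigenproblem and are cached. One-sided PSD scaling is
validated against flat white-noise levels and in-band Parseval identities.

With a 1-s window, NW = 4 means a spectral window about 8 Hz wide. Two
consequences are documented rather than hidden:

* a pure tone's per-window maximum can land anywhere inside the ±4 Hz main
  lobe, so tests assert lobe concentration rather than exact peak position;
* a narrow band such as theta (4–8 Hz) retains only ~65% of in-band power
  inside its own bins. `tbr()` therefore divides each band sum by the
  estimator's **in-band capture fraction**, calibrated once (and cached)
  from the estimator's deterministic response to unit-power sinusoids swept
  across the band. With this leakage correction, designed theta:beta ratios
  are recovered within a few percent, and the two-tone worked example
  (6 Hz at amplitude 2 vs 20 Hz at amplitude 1, analytic powers 2.0 and
  0.5) yields TBR ≈ 3.9.

**Peak normalization** divides each frequency's (and channel's) power trace
by its maximum over windows — idempotent, scale-invariant, zero columns left
at zero. The region series is the mean of the peak-normalized power over a
region's usable channels and the 4–30 Hz bins: averaging *after*
normalization keeps channels on equal footing. The aggregation order is a
documented interpretation; the normalization is within-session.

TBR uses the *unnormalized* spectrogram (band powers in µV²); the
normalized TBR divides by the same subject's no-interaction baseline mean.
Windows with zero beta power are marked invalid and excluded.

## Interbrain correlation and its null

Correlations are computed across time windows (not frequencies) between the
two subjects' region series on the shared excised timeline. Zero-variance
series yield missing values, never zero. Homologous frontal–frontal and
parietal–parietal pairs are flagged as primary endpoints; the dog temporal
region is excluded by its montage (the canine temporalis muscle precludes
usable EEG) and reported as missing.

The **pseudo-pair null** pairs each human's series with the dog series of
every other session (all $m^2 - m$ mismatched combinations, truncated to the
shortest length), within condition and day. A two-sided Mann–Whitney test
compares genuine versus pseudo-pair correlations. Validation uses 500
scaled-down null studies (4 dyads, 60-s sessions, one channel per region)
— the empirical rejection rate at $\alpha = 0.05$ stays below 7% — and
20 coupled studies at 10 dyads for power.

## MVAR and GPDC

The paired region series (1 sample/s) are demeaned and fitted with
multivariate least squares on lagged regressors; `SIG` is the residual
covariance. Order selection is BIC over 1..20 (candidates scored on the
common sample aligned at the largest lag, winner refitted in full), capped
at $n / (10k)$. Stability is checked via the companion-matrix spectral
radius; unstable fits are flagged, not silently used.

GPDC follows the canonical innovation-variance-weighted, column-normalized
definition. With
$\bar A(f) = I - \sum_r A_r e^{-i 2 \pi f r}$:

$$G_{i \leftarrow j}(f) = \frac{|\bar A_{ij}(f)| / \sigma_i}
  {\sqrt{\sum_k |\bar A_{kj}(f)|^2 / \sigma_k^2}}, \qquad
  \sigma_i^2 = \Sigma_{ii},$$

which guarantees $\sum_i G_{i \leftarrow j}(f)^2 = 1$ per source and
frequency — an algebraic identity the tests verify to $10^{-10}$. The
transfer function $H = \bar A^{-1}$, spectral density matrix
$S = H \Sigma H^H$, and magnitude-squared coherence
$C_{ij} = |S_{ij}|^2 / (S_{ii} S_{jj})$ are computed and exported alongside.

Because GPDC here operates on 1 Hz-sampled power-envelope series, its
frequency axis is 0–0.5 cycles/s of *envelope fluctuations*; the band
summary defaults to 0.01–0.4 cycles/s (configurable). The default model is
bivariate (one region, both subjects); nothing precludes fitting the joint
4-series model by passing a wider matrix to `fitMVAR`.

## Statistics layer

* **Friedman** uses the classical rank chi-square with midranks (fully tied
  blocks return statistic 0, p = 1); it is oracle-tested against the
  brute-force rank formula.
* **Mann–Whitney U** computes the exact two-sided p by enumerating all
  group assignments when both groups have at most 8 observations — valid
  under ties, unlike shortcut implementations — and a tie-corrected normal
  approximation with continuity correction otherwise; the path taken is
  recorded in the result.
* **Holm–Šídák** is the step-down $1 - (1 - p_{(j)})^{m - j + 1}$ running
  maximum, clipped to 1.
* **Exposure regression** is OLS of coupling on day with the slope's
  standard error and two-sided t p-value.
* **Logistic growth** fits $y = L / (1 + e^{-k (t - t_0)})$ by
  Levenberg–Marquardt from a multi-start grid over $(k, t_0, L)$; the
  plateau day is $t_0 + \log(19)/k$ (the 95%-of-asymptote point).
  Constant data are flagged as non-converged with no plateau reported.
* One- and two-way ANOVA comparisons are exposed as a thin wrapper over
  `stats::aov` (`groupAnova`) — classical machinery, not bespoke code.

## Validation scale and determinism

The validation suite simulates at desk scale, chosen so each property is
measured with adequate replication while the whole suite stays portable:
150-s sessions with one channel per region for direction recovery (50 seeds
per strength) and coupling monotonicity (20 seeds per strength in
{0, .25, .5, .75, 1}); 500 null studies of 4 dyads × 60 s for the
pseudo-pair size check; 300-s, 16-channel sessions at 15% contamination for
the detector's removed-fraction check (5 events per session — whole-window
excision quantizes event edges, so fewer, longer events keep the
window-level fraction comparable to the sample-level truth); 6 dyads ×
5 days for the exposure slopes and 5 replicates of 6 dyads × 10 days for
the plateau analysis. `scripts/acceptance.R` re-runs the same computations
from scratch under a caller-supplied seed.

## Known limitations

* The ANN is trained exclusively on synthetic labelled segments; no human
  annotations exist in this artifact, and the visually-identified share of
  artifact removal in a real lab workflow has no analogue here.
* The leakage-corrected TBR assumes in-band sources when inverting the
  capture fraction; strongly peaked spectra near band edges will still bias
  the ratio by a few percent.
* The per-window TBR ratio is right-skewed at low degrees of freedom; its
  median underestimates the true band-power ratio by several percent for
  single-channel series (averaging a region's channels largely removes
  this).
* Pseudo-pair stratification (same condition and day) is one reasonable
  choice among several the study design leaves open.
* GPDC inherits MVAR assumptions: linear, stationary dynamics over the
  session and an adequate order; results from unstable fits are flagged.
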