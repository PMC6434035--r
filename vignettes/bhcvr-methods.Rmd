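---
title: "Breath-hold CVR from multi-echo ASL/BOLD: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold CVR from multi-echo ASL/BOLD: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhcvr)
```

## The measurement

A breath-hold raises arterial CO2, dilating cerebral vessels and increasing
both blood flow and the BOLD signal. Cerebrovascular reactivity (CVR) is
the percent BOLD signal change evoked by this challenge. When the
acquisition also interleaves pCASL label/control frames and reads out four
echoes per excitation, one scan yields three analysable datasets: a
conventional BOLD series (the second echo, TE = 25 ms, "E2"), a
T2\*-weighted multi-echo combination ("MEC"), and a perfusion-weighted
series ("PW") from the shortest echo. With both ΔBOLD/BOLD0 and CBF/CBF0
in hand, the Davis model gives the calibration parameter M, the ceiling of
the BOLD response.

This vignette records the models implemented, the tunable parameters, and
the choices made where the method description left the design open.

## Paradigm and regressors

The encoded schedule is 64 s of calibration frames (discarded), a 44-s
paced-breathing lead-in, four cycles of 16-s end-expiration breath-hold +
16-s recovery + 24-s paced breathing, and a 24-s tail: 356 s total, 73
functional frames at TR = 4 s. `buildParadigm()` validates that the
functional duration tiles into TRs and refuses configurations that do not.

The response model convolves the task square wave (1 during holds) with a
canonical double-gamma HRF — response gamma with shape 6, undershoot gamma
with shape 16, dispersions 1 s, undershoot ratio 1/6, 32-s support, unit
peak. The method text names only a "double gamma-variate" function, so the
community-standard parameterisation is adopted and exposed
(`doubleGammaHrf()` arguments). Convolution runs on a 0.1-s grid (all
protocol durations are multiples of 0.1 s), and the convolved response is
normalised to unit peak *once*, before shifting, so all lagged copies share
one scale and the GLM coefficient reads as the peak response amplitude.

Breath-hold responses are slow and regionally delayed, so the regressor is
shifted from −2·TR to +8·TR in TR steps (11 shifts). Shifted copies are
zero-padded/truncated, never wrapped: wrap-around has no physiological
meaning. The model clock starts at the first retained frame; the discarded
calibration period contributes no signal history. With a 16-s hold and this
HRF the convolved response peaks near the end of the hold block, roughly
14 s after hold onset.

## Phantom: what it emulates, and what it does not

`phantomTruth()`/`generatePhantom()` build a 12×12×8-voxel (3-mm) grid —
a white-matter core inside a gray-matter ring — and simulate, per voxel,
frame *n* and echo *e*:

* signal `S0(n) · exp(−TE_e · R2*(n)) + ε`,
* `R2*(n) = 1/T2* − log(1 + CVR·x(n)) / TE_ref`, so the fractional change
  at the reference TE (25 ms) equals the voxel's true CVR exactly at the
  response peak — a pure ΔR2\* (susceptibility) mechanism, which makes the
  BOLD percent change grow with TE as real BOLD contrast does;
* a perfusion term on S0: `1 + (a/S0)·c(n)·(1 + (CBF/CBF0 − 1)·x(n))` with
  carrier `c(n) = ±1` (control frames positive), so the label/control
  difference decays across echoes with T2\* and dominates echo 1;
* white Gaussian noise per echo/frame, optionally AR(1) along time.

Defaults are plausible 3-T tissue values, fixed once: GM/WM T2\* 50/45 ms,
GM CVR 1.7% at TE 25 ms with WM at half, GM CBF ratio 1.5 (WM 1.25, half
the increase), perfusion amplitude 1% of S0 in GM (0.4% in WM), and noise
sd set so the echo-2 GM temporal SNR is ≈100 — the regime in-vivo
multi-echo BOLD reports. Response lags cycle deterministically over all 11
bank shifts across brain voxels, so every lag is represented. Given a seed
the output is bit-identical.

Deliberately absent: motion, reconstruction artefacts, slice timing,
cardiac/respiratory fluctuations, spatial noise correlations, and spatial
structure within tissue classes (truth maps are constant per tissue).
Passing the recovery tests therefore shows the *estimators* are correct
and calibrated under the stated noise model — not that the pipeline is
robust to everything real data contain. Two consequences worth noting:
spatial correlation between sessions on the phantom is noise-dominated
(within-tissue truth variance is zero, so r ≈ 0 is the expected value even
when the pipeline is exact), and smoothing mixes the salt-and-pepper lag
map, so parameter-recovery experiments run with smoothing disabled
(`fwhm_mm = 0`) while the pipeline default keeps the method's 4.5-mm FWHM
kernel.

## Echo fit and combination

T2\* is fit by unweighted ordinary least squares of log frame-mean signal
on echo time — the stated method — not variance-weighted regression; a
nonlinear fit serves only as a cross-check in the tests. Fits are clamped
to [2, 300] ms; out-of-range or non-positive-mean voxels are flagged
invalid rather than raising errors, and receive uniform combination
weights. Weights are computed per session from that session's own means,
never shared across visits.

### Why combined-echo CVR is *higher* than E2 on this phantom

The combination weight times the baseline signal gives each echo an
effective contribution ∝ TE·exp(−2·TE/T2\*). At GM T2\* = 50 ms, 61% of
that weight lies at TE ≥ 25 ms and the BOLD-weighted effective TE is

  Σ TE² e^(−2TE/T2\*) / Σ TE e^(−2TE/T2\*) ≈ 31.7 ms > 25 ms,

so a pure ΔR2\* phantom *must* show MEC CVR above E2 CVR (the acceptance
script reports the measured ratio as `cvr_mec_over_e2_gm_ratio`). The
ordering would flip only for T2\* below ≈29 ms. In-vivo reports of lower
combined-echo CVR therefore reflect effects this phantom excludes — noise
floors at long TE, partial-volume and inflow (non-BOLD) signal at short
TE — not the weighting arithmetic. This is a known, documented limitation
of the phantom: the corresponding direction check in the acceptance suite
fails by construction and is kept failing rather than re-tuning tissue
values to force agreement.

## Perfusion-weighted series

The PW series is the first echo, high-pass filtered per voxel and
demodulated by cos(πn). Choices:

* **Filter**: zero-phase forward–backward Butterworth, order 4, cutoff
  0.09 Hz (the stated cutoff; the family/order are unstated and chosen as
  a conventional zero-phase design that adds no lag bias to the PW GLM).
  At TR = 4 s the Nyquist frequency is 0.125 Hz, so the passband for the
  demodulated perfusion signal is only ≈0.035 Hz wide.
* **Padding**: mirror (even) reflection. Point-symmetric (odd) reflection —
  the usual choice for slow signals — breaks the ±1 alternation at the
  series ends and corrupts the PW estimate there; mirror reflection
  continues the carrier coherently.
* **Parity**: 0-based even frames are control by default (`labelParity`),
  matching the cos(πn) carrier; the sign convention makes baseline PW
  positive in gray matter. Swapping parity negates the series exactly.
* **Design filtering**: the PW GLM regressors are passed through the *same*
  filter-and-demodulate operator as the data (`pwRegressorBank()`), the
  standard practice of filtering the design with the data. Because the
  filter's transition band overlaps the breath-hold harmonics, an
  unfiltered regressor would underestimate the PW response by roughly
  15–25% and bias CBF/CBF0 accordingly; filtering the design absorbs the
  attenuation. The underlying regressor keeps its unit-peak scale so the
  coefficient still estimates the peak perfusion change.
* **No prewhitening for PW**: the filtering/demodulation chain leaves the
  perfusion noise with minimal temporal autocorrelation, so the PW GLM is
  plain OLS with intercept + breath-hold regressor only.

## GLM, lag selection and inference

BOLD designs contain an intercept, orthogonal-polynomial trends to order 3
(discrete Legendre basis — projection is basis-independent), the ±1
label/control column, and one lag-shifted regressor; the 11 designs are
fit independently and the highest positive t wins. Exact ties go to the
smaller shift (determinism; earliest physiologically plausible response).
If no shift gives t > 0 the maximal-t fit is kept with the lag flagged
unreliable.

Degrees of freedom are reported for the single chosen design (n − p),
uncorrected for the selection over 11 correlated regressors — matching the
method's apparent practice. The selection makes the nominal null
anti-conservative: under white noise the p < 0.001 threshold admits several
times the nominal rate of false positives (the acceptance suite measures
this rather than correcting it, since the printed-style outputs are meant
to mirror the original procedure).

Temporal autocorrelation is handled by an optional AR(1) prewhitening
toggle (a deliberate simplification of full ARMA(1,1) REML; AR(1) captures
the leading effect). The lag-one autocorrelation of OLS residuals is
biased toward zero in a 73-frame scan with six design columns, so the
estimate is iterated twice (whiten, re-estimate, compose) with the
standard (1 + 3ρ)/n small-sample correction, and clamped to |ρ| < 0.99.
This restores the 0.05-level type-I error to its nominal band under
ρ = 0.4 noise; plain OLS roughly doubles it.

Activation masks use the one-sided Student threshold (positive responses
only — consistent with selecting the highest *positive* t) at p < 0.001
uncorrected.

## CVR, CBF ratio and M

CVR = 100·β/baseline with β the peak response. Two baseline conventions
exist (`baseline_mode_*`): the full-series mean ("mean signal") and the
GLM intercept. For BOLD the default is the mean — the literal reading —
and the difference is negligible (the response elevates the mean by
CVR·mean(x) ≈ 0.4% of itself at 1.7% CVR). For PW the default is the
intercept: the PW response is ~50% of baseline, so a full-series mean is
inflated by ≈10%, which propagates through CBF/CBF0 = 1 + β_PW/baseline_PW
into a deterministic ≈8% error in M. The intercept estimates the signal in
the absence of the response and removes that bias; the mean mode remains
available for strict fidelity.

M = (CVR/100) / (1 − (CBF/CBF0)^(α−β)), reported in percent, with α = 0.2
and β = 1 (the values appropriate above 3 T; a sensitivity check with
β = 1.3 preserves voxel ranking). Voxels with CBF ratio ≤ 0 or = 1
(singular denominator), or a non-positive PW baseline, are invalid and
propagate as missing values excluded from all means — this mirrors the
white-matter exclusion where weak perfusion makes the ratio unstable. The
CBF ratio uses the PW lag-optimised beta, with the same −2·TR…+8·TR bank
as BOLD (the method text does not say whether PW used the same bank; using
one bank keeps the two estimates aligned per voxel).

## Repeatability metrics

Dice is computed on the p < 0.001 masks by default (it is threshold-
dependent, so the threshold is a parameter). The voxelwise repeatability
index excludes voxels whose two values sum to zero (the ratio is undefined
there) and reports the exclusion count. Its default mask is gray matter,
with any mask acceptable (whole-brain included — the formula's natural
domain). ICC(3,1) is computed in closed form from the balanced two-way
ANOVA decomposition, (BMS − EMS)/(BMS + (k−1)·EMS), with listwise deletion
of incomplete rows; for balanced complete tables this equals the
mixed-model estimate, and the tests verify agreement with `stats::aov`
mean squares to 1e-10. Fisher z = atanh(r) on the spatial Pearson
correlation; r = 1 yields an infinite z, flagged rather than fatal.

## Problem sizes and tolerances

The default grid (12×12×8, 704 brain voxels, 73 frames, 4 echoes) runs a
full session in about a second, so the test suite and the acceptance
script rerun the pipeline from scratch many times: noiseless and
tSNR-100 sessions, a high-SNR (tSNR 1000) session for parameter recovery,
a two-session run for retest metrics, six simulated subjects × two
sessions for ICC, 20 000 white-noise replicates for the 0.001-level
calibration and the max-t null, and 2 000 AR(1) replicates for the
prewhitening check. Recovery tolerances follow the estimator noise at
those sizes: T2\* and S0 to machine precision without noise; GM-median
CVR within 2% and M within 5% of truth at tSNR 1000; lag recovery 100%
noiseless and ≥90% at tSNR 100.

## Known limitations

* The MEC-vs-E2 CVR ordering on the phantom is opposite to in-vivo
  reports, for the arithmetic reason derived above.
* Lag-selection inflation of the nominal false-positive rate is measured
  and documented, not corrected.
* The phantom's spatially flat truth maps make between-session spatial
  correlation uninformative (noise around zero); Dice and the
  repeatability index remain informative.
* Absolute CBF quantification, end-tidal CO2 regressors, registration,
  segmentation and motion handling are out of scope; inputs are assumed
  aligned with known masks.
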