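# bhcvr

Breath-hold cerebrovascular reactivity (CVR) analysis for simultaneous
multi-echo ASL/BOLD fMRI, in R.

Breath-holding raises arterial CO2 and dilates cerebral vessels; the
resulting BOLD signal change per unit stimulus is a clinically useful index
of vascular health. A multi-band multi-echo pCASL/BOLD acquisition delivers,
in one scan, four echoes per frame (TE = 9.1/25/39.6/54.3 ms at TR = 4 s)
plus alternating label/control frames carrying a perfusion signal. `bhcvr`
implements the full analysis chain for such data — and, because deposited
scanner data for this protocol are not publicly available, ships a digital
phantom with known ground truth so every stage is testable end to end. It is
aimed at fMRI methods researchers who want a scripted, reproducible
desk-scale implementation of the method.

## What it computes

**T2\*-weighted echo combination.** The frame-mean signal of each echo is
fit voxelwise by log-linear regression to S(TE_n) = S0 · exp(−TE_n / T2\*),
and echoes are summed with weights

    w_n = TE_n exp(−TE_n / T2*) / Σ_n TE_n exp(−TE_n / T2*)

giving the "MEC" dataset; the second echo alone ("E2", TE = 25 ms) mimics a
conventional BOLD acquisition.

**Perfusion-weighted (PW) series.** The first echo is high-pass filtered at
0.09 Hz (zero-phase Butterworth) and demodulated by cos(πn), moving the
label/control alternation to baseline; positive PW means control > label.

**Lag-optimised breath-hold GLM.** The task square wave is convolved with a
double-gamma HRF, shifted from −2·TR to +8·TR in TR steps (11 regressors),
and each voxel keeps the shift with the highest positive t-score. Nuisance
columns: intercept, 3rd-order polynomial trends, and the ±1 label/control
column (BOLD only). Optional AR(1) prewhitening models temporal
autocorrelation. Activation is thresholded one-sided at p < 0.001
(uncorrected).

**CVR and the Davis M parameter.** CVR = 100 · β / baseline (the regressor
is unit-peak scaled, so β is the peak response). With CBF/CBF0 from the PW
data and CMRO2/CMRO2,0 = 1 during hypercapnia, the Davis model inverts to

    M = (ΔBOLD/BOLD0) / (1 − (CBF/CBF0)^(α−β)),   α = 0.2, β = 1.

**Test–retest metrics.** Dice overlap of thresholded activation masks,
voxelwise repeatability 1 − mean |x1 − x2| / |x1 + x2|, ICC(3,1) from the
two-way mixed ANOVA decomposition, and Fisher-z spatial correlation.

## Worked example

```r
library(bhcvr)
paradigm <- buildParadigm()     # 64 s calibration + 44 s lead-in +
paradigm                        # 4 x (16 BH + 16 recovery + 24 paced) + 24 s
#> Paradigm: 4 x 16 s breath-hold cycles
#>   lead-in 44 s | recovery 16 s | paced 24 s | tail 24 s | calibration 64 s
#>   TR 4 s | total 356 s | 73 functional frames

truth <- phantomTruth(seed = 7)            # GM ring / WM core, tSNR ~100
series <- generatePhantom(truth, paradigm)
series
#> MultiEchoSeries: 12 x 12 x 8 grid, 73 frames, 4 echoes
#>   TE 9.1/25/39.6/54.3 ms | TR 4 s | even-control

res <- runSession(series, truth@gmMask, truth@wmMask, paradigm,
                  fillRunConfig(list(fwhm_mm = 0)))
res$activation$MEC
#> ActivationResult: 704 voxels in mask, dof = 67
#>   active at p < 0.001: 696 | unreliable lag: 0
res$maps$MEC
#> CvrMMaps (alpha = 0.2, beta = 1): 704 valid voxels
#>   median CVR 2.07% | median CBF ratio 1.6 | median M 6.34%
round(c(tsnr_e2  = mean(res$tsnr$E2[truth@gmMask]),
        tsnr_mec = mean(res$tsnr$MEC[truth@gmMask]),
        tsnr_pw  = mean(res$tsnr$PW[truth@gmMask])), 1)
#>  tsnr_e2 tsnr_mec  tsnr_pw
#>     99.4    153.9      3.3
mean(res$activation$MEC@lagS[truth@gmMask] == truth@lagS[truth@gmMask])
#> [1] 0.9980469
```

The combined-echo dataset has ~1.5× the echo-2 temporal SNR, the PW series
sits near tSNR 3 (perfusion signal is intrinsically weak), and the lag sweep
recovers 99.8% of the injected hemodynamic delays at this noise level. Note
that on this phantom the combined-echo CVR is *higher* than the echo-2 CVR
(effective TE of the T2\*-weighted sum exceeds 25 ms at GM T2\* = 50 ms);
see the vignette for why in-vivo reports can show the opposite ordering.

`runPipeline()` orchestrates the same stages from a YAML config (optionally
two sessions plus retest metrics, NIfTI/TSV artifacts and a stage log), and
`inst/scripts/run_pipeline.R` wraps it for shell use.

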