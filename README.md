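# ppgwave

Wavelet tools for photoplethysmography (PPG): baseline-drift suppression by
multiresolution analysis and automatic systolic-peak detection from
quadratic-spline wavelet modulus maxima, with detector evaluation, pulse
oximetry (SpO₂), a seeded synthetic-PPG generator, and a command-line
interface.

## The problem

A pulse oximeter's PPG waveform carries one systolic peak per heartbeat;
peak positions and amplitudes feed pulse-rate, pulse-rate-variability and
SpO₂ estimation. Respiration and body movement superimpose nonstationary
low-frequency (< 1 Hz) baseline wander and motion artifacts that distort
amplitudes and derail naive peak pickers. `ppgwave` implements a two-stage
hybrid method for users who need reliable beat positions from ambulatory or
otherwise drift-contaminated recordings:

1. **Suppression.** The signal is processed in 1024-sample windows and
   decomposed with the sym8 wavelet to the deepest level the window supports,

   Lmax = fix( log₂( N / (lw − 1) ) ),

   with N the window length and lw the filter tap count (N = 1024, lw = 16
   ⇒ Lmax = 6; at 100 Hz the level-6 approximation covers ≈ 0–0.8 Hz). That
   approximation is the baseline estimate and is subtracted from the raw
   trace.

2. **Detection.** The corrected signal is decomposed with the undecimated
   (à trous) quadratic-spline wavelet (Mallat–Zhong filters
   h = (0.125, 0.375, 0.375, 0.125), g = (2, −2)) into 5 levels. A pulse's
   upstroke/downstroke produces an opposite-sign pair of modulus maxima of
   the detail coefficients W₄, W₅, where pulse energy concentrates at
   100 Hz. Maxima are thresholded per level at

   ε = 0.5 · mean( per-segment maxima of |W| ),   N = int(L/t) segments of t = 256 samples,

   retained only if they persist on both levels, paired (isolated maxima are
   artifact-like and dropped; of two pairs within the 200 ms refractory only
   the larger survives), and each pair's zero-crossing is refined to the
   signal argmax nearby — the reported peak.

Detector quality is scored against reference beats as
**Error = (FP + FN) / RB × 100 %** (RB real beats, FP false detections, FN
missed beats), and dual-wavelength recordings yield SpO₂ per beat via the
ratio of ratios R = (ΔI′/I′)/(ΔI/I) with a linear calibration
SpO₂ = A·R + B.

## Worked example

```r
library(ppgwave)

cfg <- synthetic_config(duration = 60, regime = "walking", seed = 7)
rec <- generate_ppg(cfg)
rec
#> <synthetic_ppg> 60 s @ 100 Hz, 74 true beats, regime=walking, seed=7

# detection on the raw, drift-contaminated trace
evaluate_detection(detect_peaks(rec$signal), rec$peaks)
#> <evaluation_result> RB=74 TP=8 FP=0 FN=66 error=89.19%

# the same trace after baseline suppression
evaluate_detection(detect_peaks(correct_baseline(rec$signal)), rec$peaks)
#> <evaluation_result> RB=74 TP=72 FP=0 FN=2 error=2.70%
```

The walking-regime drift (twice the pulse amplitude) swamps the adaptive
threshold on the raw trace, so most beats are missed; after multiresolution
suppression the same detector recovers 72 of 74 beats with no false
positives. On a dual-wavelength record the configured ratio of ratios is
recovered and mapped through the calibration line:

```r
dual <- generate_dual_channel(synthetic_config(duration = 30, seed = 3), ratio = 0.6)
compute_spo2(pulse_features(dual$red, dual$peaks),
             pulse_features(dual$ir, dual$peaks), list(A = 25, B = 60))
#> <spo2_result> 37 beats, median SpO2 = 74.99 (median R = 0.5997)
```

## Command line

`exec/ppgw` exposes the pipeline as subcommands `simulate`, `correct`,
`detect`, `evaluate`, `spo2` and `run`; signal files are
`time_s,amplitude` CSVs (or a single `amplitude` column with `--fs`), peak
files one **0-based** sample index per line, results JSON on stdout:

```sh
exec/ppgw simulate --regime walking --duration 60 --seed 7 --out sig.csv --truth truth.txt
exec/ppgw detect   --input sig.csv --out peaks.txt
exec/ppgw evaluate --detected peaks.txt --reference truth.txt --fs 100
```

## Documentation

The methods vignette (`vignettes/ppg-wavelet-methods.Rmd`) describes the
model, the parameter choices and their units, what the synthetic generator
does and does not emulate, and known limitations.
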