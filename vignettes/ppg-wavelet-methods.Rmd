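---
title: "Wavelet baseline suppression and modulus-maximum peak detection for PPG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet baseline suppression and modulus-maximum peak detection for PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgwave)
```

## The signal model

A photoplethysmogram is modeled as an additive mixture

$$x(t) = p(t) + b(t) + a(t) + w(t),$$

where $p$ is the quasi-periodic pulse wave (energy concentrated in roughly
1–10 Hz at resting heart rates), $b$ is baseline wander — slow (< 1 Hz)
respiratory and postural drift of the DC level — $a$ collects transient
motion-artifact bumps whose dominant energy is likewise low-frequency, and
$w$ is wideband noise (largely removed by acquisition front-ends, so assumed
small). The two stages of the package attack $b + a$'s low-frequency part
and then locate the systolic apexes of $p$.

## Stage 1: multiresolution baseline suppression

`correct_baseline()` processes the trace in non-overlapping 1024-sample
windows (`block_len`, default 1024; roughly 10 s at 100 Hz, long enough to
resolve sub-Hz drift, short enough to track nonstationarity). Each window is
decomposed with the sym8 wavelet — a least-asymmetric orthogonal wavelet
whose smooth scaling function resembles pulse morphology — to the deepest
level the window supports,

$$L_{\max} = \mathrm{fix}\,\log_2\frac{N}{l_w - 1},$$

with $N$ the window length and $l_w = 16$ the sym8 tap count. For $N = 1024$
this gives $L_{\max} = 6$; the level-6 approximation band at 100 Hz spans
about 0–0.78 Hz, i.e. the drift band. (The truncation is read as
$\mathrm{fix}(\log_2(N/(l_w-1)))$: the alternative grouping
$\mathrm{fix}(\log_2(N/l_w - 1))$ would give 5 levels for a 1024-sample
window and contradict the 6-level working point the method is built around.)
The approximation is the baseline estimate; subtracting it yields the
corrected window.

**Realization.** The decomposition is computed as an undecimated transform
(MODWT) on a half-point symmetric reflection of the window, truncated back
to the window length. This choice has three consequences the package relies
on: the approximation and every detail are full-length series; the
multiresolution components sum back to the input to machine precision (the
test suite asserts $10^{-8}$ relative, observed $\sim 10^{-12}$); and the
analysis–synthesis cascade is zero-phase, so the baseline estimate is
time-aligned with the drift it tracks. Symmetric extension keeps edge
artifacts confined to the outer samples, which is why spectral assertions in
the tests measure the interior 80 % of samples.

**Window joints.** Each window's baseline is estimated from the window plus
a 256-sample margin of *real* neighboring samples (mirror extension is only
used where no neighbors exist, at the record ends). Without the margin,
consecutive baseline segments meet with small steps that masquerade as sharp
edges to the detector; with it, corrected windows join smoothly while each
window still gets its own adaptively chosen depth — a final fragment shorter
than 1024 samples simply recomputes $L_{\max}$ for its own length, and a
fragment too short for even one level (under $2 l_w$ samples) falls back to
mean subtraction.

## Stage 2: quadratic-spline modulus-maximum detection

`detect_peaks()` uses the à trous (undecimated) quadratic-spline wavelet
transform, `qspline_decompose()`, with the Mallat–Zhong filter pair

$$h = (0.125,\ 0.375,\ 0.375,\ 0.125), \qquad g = (2,\ -2).$$

$g$ is a first difference ($\sum g = 0$, so any DC offset vanishes from all
detail levels), $h$ a B-spline smoother; at level $i$ both are applied with
$2^{i-1}-1$ zeros between taps. The published tap values for this filter
family differ by per-level $\sqrt{2}$ normalization factors across sources;
the package fixes the plain dyadic values above because the detector is
exactly invariant to per-level rescaling — its threshold is computed from
the same coefficients it gates — and a test asserts that invariance, so the
normalization convention cannot change any detection.

A smooth pulse produces, at each scale, a positive maximum of $W_i$ on the
upstroke and a negative one on the downstroke, with a zero-crossing at the
apex. At 100 Hz the pulse band maps to levels 4 and 5 (`levels_used`,
default `c(4, 5)`; a 2 Hz probe tone concentrates more than half of its
total detail RMS there, asserted in the tests), while wideband noise stays
in levels 1–2 — the ground for detecting on $W_4$, $W_5$ only.

The detection steps, per 1024-sample analysis block:

1. **Adaptive threshold** (`compute_threshold`): the magnitude series of
   each used level is split into $N = \mathrm{int}(L/t)$ segments of
   $t = 256$ samples (`seg_len`; at least one heartbeat at any plausible
   rate), and $\varepsilon = 0.5 \cdot \mathrm{mean}(\text{segment maxima})$
   (`threshold_factor`, default 0.5). Segmentation makes the threshold
   follow amplitude nonstationarity within the block. The threshold is
   computed per level, because coefficient scales differ across levels.
2. **Modulus maxima** (`extract_modulus_maxima`): strict local maxima of
   $|W_i|$ exceeding $\varepsilon_i$, carrying the coefficient's sign.
3. **Cross-level persistence** (`cross_level_retain`): a maximum is kept
   only if a same-sign maximum exists on the other level within
   `persistence_window` = 16 samples (the level-4 support scale) — genuine
   pulse transitions persist across scales, noise spikes do not. Matching is
   greedy by distance with each partner consumed once.
4. **Pair selection** (`select_pairs`): isolated maxima — no opposite-sign
   companion within `pairing_window_ms` = 300 ms (wider than a systolic
   upstroke, narrower than a beat at 200 bpm) — are artifact-like and
   dropped; adjacent opposite-sign maxima form pairs. Two pairs whose
   zero-crossings fall within the `refractory_ms` = 200 ms physiological
   minimum cannot both be beats: the larger-amplitude pair survives
   (resolved from the largest amplitude down, so a pair suppressed by a
   stronger one does not itself suppress others). Pair polarity order is not
   enforced; reflective-probe PPG can arrive inverted and the zero-crossing
   rule works either way.
5. **Localization** (`locate_peaks`): each pair's zero-crossing — the actual
   sign change of $W_4$ between the two maxima (midpoint fallback when no
   coefficients are supplied) — is refined to the argmax of the original
   signal within `refine_window_ms` = 100 ms, covering the residual
   alignment slack of the coarse scales.

**Alignment.** Causal à trous filtering delays level $i$ by
$1.5\,(2^{i-1}-1) + 0.5 \cdot 2^{i-1}$ samples; each detail series is
shifted to compensate, so a symmetric pulse's zero-crossing lands on its
apex within one sample at every level (asserted in the tests). Blocks are
analyzed with a 256-sample context margin so a pair straddling a block edge
is seen whole; each block emits only the peaks inside its own span, and a
final refractory pass over the assembled peak list (largest amplitude first)
covers the joints.

The full detector is deterministic and *exactly* invariant — to the index —
under amplitude scaling and DC offset, because thresholds and coefficients
scale together and $g$ annihilates constants.

## Evaluation

`match_peaks()` matches detected against reference peaks one-to-one within
±150 ms (`tolerance_ms`; below half a beat interval at 200 bpm, generous for
apex jitter). Because both sequences are sorted, a maximum matching can
always be realized without crossings; the implementation computes it by
dynamic programming and the tests verify it against exhaustive enumeration.
`detection_error()` reports $100(FP+FN)/RB$ rounded half-up to two decimals,
matching conventional table formatting; pooling consistency (the error of
pooled counts equals the pooled error) is asserted in the tests.

## SpO₂

With two wavelengths, each beat yields normalized pulsatile ratios
$\Delta I / I_{\max}$ (peak minus preceding trough, over peak); their
quotient $R$ enters either the linear calibration $A R + B$ (default — the
logarithmic ratio is nearly linear at physiological pulsatilities of a few
percent) or the exact form
$A \,\lg(1-\Delta I'/I'_{\max})/\lg(1-\Delta I/I_{\max}) + B$
(`form = "log"`). $A$ and $B$ come from device calibration and have no
defaults. Beats with zero pulsatility in the denominator channel, or with a
ratio at or above 1 in the log form (outside the logarithm's domain), are
skipped with a warning rather than clamped; the per-record summary is the
median across beats, robust to single-beat artifacts.

## The synthetic generator

`generate_ppg()` emulates exactly the features the pipeline is sensitive to:

* **Pulse train**: beat intervals $\mathcal{N}(60/\mathrm{hr}, \cdot)$
  truncated positive; each beat stamps a two-Gaussian template — systolic
  bump ($\sigma = 60$ ms, unit height) plus dicrotic bump (+300 ms, 35 %
  height, $\sigma = 100$ ms), a standard morphology surrogate. Ground-truth
  peaks are the actual apexes of the clean component.
* **Drift**: sub-1-Hz sinusoids with random phases plus an amplitude-scaled
  centered random walk (a $1/f^2$ spectrum, overwhelmingly sub-Hz).
* **Artifacts**: Poisson events, each a Gaussian bump of 0.5–1.5 s duration
  and random sign.
* **Noise**: white Gaussian, small by default (front-end hardware is assumed
  to have removed wideband noise).

The three regime presets encode a difficulty ladder: `sitting` (drift 5 % of
pulse amplitude at the 0.25 Hz respiratory rate, no artifacts),
`raising_hand` (drift comparable to the pulse at 0.1–0.3 Hz), `walking`
(drift at twice the pulse amplitude plus 4 artifact events/min, noise SD
0.02). These were fixed once as plausible renderings of the three postures;
the walking preset is deliberately harsh, so raw-trace errors on it are far
larger than on any well-acquired recording — the regimes are meant to
exercise the corrected-versus-raw *ordering*, not to calibrate absolute
error levels. All randomness flows from one seed per record (restored
afterwards, so the generator never perturbs the caller's RNG stream), and
components are returned separately so tests can assert exact additivity.

What the generator does **not** emulate: true cardiovascular dynamics
(no Windkessel model), reflected-wave morphology changes, sensor saturation
and clipping, heartbeat-synchronous artifact coupling (cadence locking while
walking), or ectopic beats. Passing tests on synthetic data therefore
demonstrate the algorithmic contracts — band separation, invariances,
matching, error arithmetic — not clinical-grade performance on real
recordings, which depend on morphologies and artifact structure outside this
model. `generate_dual_channel()` shares one beat train across two channels
and solves the AC fractions exactly so the per-beat ratio of ratios equals
the configured target at the nominal apex; the recovery tolerance (0.02) in
the tests absorbs beat-overlap and noise effects.

## Numerical choices and degenerate inputs

* Boundary handling is half-point symmetric everywhere; assertions about
  spectra and reconstructions target interior samples.
* The decomposition-level rule errors ("no valid decomposition level") when
  a window cannot host one level, rather than returning 0.
* `compute_threshold` ignores a trailing remainder shorter than one
  segment; a flat (all-zero-coefficient) block yields a zero threshold and
  the block is skipped rather than thresholded at 0.
* Argmax ties in localization resolve to the earliest index; duplicate
  localizations collapse; the final refractory pass keeps the
  higher-amplitude peak.
* Peak indices are 1-based inside R and 0-based in files, converted at the
  I/O boundary only.

## Problem sizes

The test suite and the ensemble checks run on 20–60 s records at 100 Hz
(2 000–6 000 samples), 20-seed ensembles for the clean-detection and
walking-regime claims, and length-≤128 signals for brute-force oracle
equality — sizes at which every property is measured in seconds on one core
while still spanning multiple analysis blocks and hundreds of beats.

## Known limitations

* The detector's configuration is tuned to 100 Hz sampling; at other rates
  the 5-level depth and the levels-4/5 choice must be revisited (`levels`
  and `levels_used` are exposed, but no automatic rate adaptation is done).
* Suppression removes everything below ≈ 0.8 Hz, including any genuine
  cardiac content at extreme bradycardia (< 48 bpm fundamental), though
  harmonics generally preserve detectability.
* Motion artifacts with substantial in-band (1–10 Hz) energy are outside
  the suppression stage's reach by design; only their low-frequency part is
  removed.
* Evaluation requires externally supplied reference annotations; the
  package takes no stance on how ambiguous beats were adjudicated.
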