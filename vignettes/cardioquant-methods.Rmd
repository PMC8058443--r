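---
title: "Quantifying cardiomyocyte phenotypes with cardioquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiomyocyte phenotypes with cardioquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioquant)
```

# Scope

`cardioquant` implements the quantitative layer of a cardiotoxicity
phenotyping workflow for isolated ventricular cardiomyocytes: action-potential
(AP) features and beat-to-beat repolarization variability from current-clamp
voltage traces; Ca²⁺-transient kinetics, caffeine-based SR-content estimation
and resting SR-instability events from Fluo-4 fluorescence traces; Ca²⁺-spark
detection and parameterization on confocal line-scan (xt) images with the
derived spark-mass / SR-leak / ember indices; a spatial-FFT T-tubule
regularity index for 2D cell images; and the group-comparison statistics used
to contrast treatment groups. Each analysis stage has a matching synthetic-data
generator with closed-form ground truth, so the whole pipeline is testable
without any microscope.

This vignette documents the models, the tunable parameters (with units and
defaults), the numerical choices, and what the synthetic data do and do not
emulate.

# Electrical activity

## AP features

APs are segmented at take-off, defined as the time of maximal upstroke
velocity dV/dt~max~ (the earliest index attaining the maximum within
numerical tolerance, so flat-topped discretized upstrokes are handled
deterministically). When stimulus annotations are present, take-off is
searched within 20 ms after each stimulus; otherwise upstrokes are detected
where dV/dt exceeds 10 V/s, grouped with a 100 ms refractory gap. The two
paths agree exactly on clean data, which the test suite checks.

APD at repolarization fraction *x* is the time from take-off to the first
crossing of

$$V_{x} = V_{peak} - x\,(V_{peak} - E_{diast}),$$

with linear interpolation between samples for sub-sample resolution.
The repolarization reference span is peak minus diastolic potential (not peak
minus plateau), the common convention. `E_diast` is the mean over a 50 ms
window ending 5 ms before take-off (both configurable); a first beat without
pre-stimulus context falls back to the late-diastolic tail of its own segment.
A beat that never reaches the requested level yields `NA` — features are
flagged missing, never extrapolated. Optional moving-average smoothing before
differentiation is off by default; it is unnecessary on clean traces and any
smoothing biases dV/dt~max~ downward.

## DADs and EADs

A delayed afterdepolarization is a diastolic depolarizing deflection with
baseline-to-peak amplitude ≥ 1 mV (inclusive). The diastole of each beat runs
from APD₉₀ completion plus 20 ms to 20 ms before the next take-off. Candidate
deflections must exceed the local diastolic baseline (the median) by 0.5 mV on
a 2 ms-smoothed copy for at least 5 ms, with sub-threshold gaps under 10 ms
merged; their amplitude is then measured on the *raw* trace so the 1 mV rule
is applied exactly. A run already above threshold at the window start is the
repolarization tail and is discarded. With these settings the detector scores
perfect recall and precision on simulated trains with 1.5 mV events at 0.2 mV
noise (±20 ms matching), which the tests assert.

EADs are flagged where the potential turns upward again during repolarization
(between the peak and the APD₉₀ crossing) and rises by at least a configurable
deflection (default 1 mV) from a local minimum, with hysteresis so one
continuous rise produces one event. No amplitude rule for EADs is fixed in
the literature this pipeline follows; the threshold is exposed as a setting
and not asserted against a reference value.

## Short-term variability

Beat-to-beat repolarization variability is summarized as the short-term
variability of APD₉₀, the mean orthogonal deviation of consecutive-beat pairs
from the Poincaré identity line:

$$\mathrm{STV} = \sum_{n} |APD_{n+1} - APD_n| \,/\, (n_{beats}\sqrt{2}),$$

conventionally over 30 consecutive steady-state beats. Both the
$n\sqrt{2}$ denominator (the form in the STV methods literature, the default
here) and a plain $2n$ denominator circulate in the applied literature;
`stv(..., denominator = "two")` selects the alternative, and the choice is
recorded in the result. STV is non-negative, translation-invariant and scales
linearly with the APD sequence — all property-tested. `stv_apd_regression()`
fits per-cell STV against APD₉₀ by ordinary least squares, the standard way
to ask whether variability increases merely because APD lengthened.

# Ca²⁺ transients

Raw fluorescence is normalized as $F/F_0 = (F - bg)/(F_0 - bg)$ after
background subtraction. $F_0$ is the diastolic fluorescence: for paced traces
the median over the last 20% of each pre-stimulus cycle; for resting traces
the median after two rounds of excluding samples more than 3 robust SDs above
the median, so sparse spontaneous events do not bias the baseline. The
normalization is invariant to affine gain/offset changes given a correct
background, and a background at or above the diastolic level is rejected as
non-physical.

Per-transient features: amplitude (peak minus pre-stimulus diastolic level,
ΔF/F₀), time-to-peak, and the half-decay time T₀.₅ from the peak to the
interpolated 50% crossing. For a mono-exponential decay T₀.₅ = τ ln 2 exactly;
the estimator reproduces this to within one sample, which anchors the test
suite. A transient that has not decayed below 50% before the next stimulus
gets `NA` rather than an extrapolated value. Steady-state summaries average
the last five transients by default.

The caffeine pulse is analyzed as: SR content CaSR = caffeine-transient
amplitude (ΔF/F₀), and NCX function as the decay constant of a least-squares
fit of $A e^{-t/\tau} + C$ (Levenberg–Marquardt, log-linear start values) to
the post-peak segment, fitted over 95% of the available decay. A segment that
does not decay is an error, never a silent fallback. Noiseless recovery is
exact to ~1 ms at τ = 800 ms and within 5% at 5% noise.

Resting SR instability: the resting level F_rest and its SD are estimated
with two rounds of 3 SD exclusion (events inflate a naive SD). A Ca²⁺ wave is
an excursion exceeding `sd_cutoff` (default 3, strict) resting SDs for at
least 3 consecutive samples — the run-length requirement suppresses
single-sample threshold touches, and the detector produces zero false
positives on 100 seeded noise-only traces in the tests. Events are labeled
`resting_transient` instead of `wave` when their ΔF/F₀ amplitude reaches 50%
of the cell's paced transient amplitude (or 0.5 ΔF/F₀ absent a paced record);
no quantitative wave/resting-transient boundary is established in the
literature this follows, so the criterion is an explicit, configurable
assumption. `normalize_to_ctrl()` expresses treated-group means relative to
control per pacing cycle length with propagated standard errors.

# Ca²⁺ sparks

## Detection

Detection re-implements the classic line-scan spark-detector design at
contract level, with the criterion `cri = 3.8` as default:

1. per spatial pixel, baseline mean μ and SD σ of the temporal signal are
   estimated with three rounds of excluding samples above μ + cri·σ;
2. pixels of a 3×3-boxcar-smoothed copy exceeding μ + cri·σ are flagged as
   cores;
3. cores grow to their connected regions above μ + (cri−1)·σ;
4. connected labeling merges overlapping regions;
5. regions smaller than 4 pixels are discarded.

Because σ comes from the raw temporal signal while the threshold is applied
to the smoothed copy (whose noise SD is ~3× lower), the effective test is
~11 noise SDs of the smoothed image: the false-positive rate on spark-free
images is essentially zero (< 0.05 events/image over 100 seeded null frames,
asserted), while sparks of amplitude ≥ 0.5 ΔF/F₀ at 0.1·F₀ noise are smoothed
to ~4.5 raw SDs and detected with recall ≥ 0.95. The smoothing kernel, growth
step, and minimum area are assumptions of this implementation (the original
plugin's internals are not published at that granularity) and are all
configurable. Raising `cri` can only reduce the number of detections
(property-tested), and detection is fully deterministic.

## Parameterization

All parameters are measured on the ΔF/F₀ image (per-column baseline, after
background subtraction). The temporal profile is the spatial average over the
event's half-maximal width and the spatial profile the temporal average over
its half-maximal duration; for (near-)separable events such averaging rescales
but does not reshape the profiles, so FWHM and FDHM are read off by
interpolated half-maximum crossings. Amplitude is the peak of the low-noise
temporal profile corrected by the exact attenuation factor of averaging a
Gaussian spatial profile over the measured half-max columns — the factor is
computed per event from its own measured FWHM, which removes the ~20%
averaging bias while keeping the noise suppression of the profile (median
amplitude error ~3% in the recovery tests). Full width and duration (FW, FD)
are measured at baseline + 2 local noise SDs, since a true zero-crossing is
undefined in noise. Time-to-peak runs from the onset (last sub-2SD profile
sample before the peak) to the peak; the decay constant comes from a
log-linear mono-exponential fit from the peak over the contiguous
supra-threshold stretch. Events whose profiles leave the image before
crossing half-maximum are flagged `partial` and excluded from summaries, so
edge events cannot bias FWHM/FDHM statistics.

Derived indices follow their printed definitions exactly:
spark mass = amplitude · 1.206 · FWHM³ (ΔF/F₀·μm³); frequency =
in-focus events · s⁻¹ · (100 μm)⁻¹; SR leak = mean spark mass × frequency;
sparks are *in focus* iff amplitude > 0.3 (strict) and *embers* iff
FDHM > 20 ms (strict). The identities hold to machine precision on every
detected spark, and the boundary cases (amplitude 0.3, FDHM 20 ms) are
excluded, as the strict inequalities require. Multi-frame acquisitions (e.g.
ten 512-line xt frames per cell) are concatenated along time, so a 10-frame
stack at 2 ms/line contributes 10.24 s to the frequency denominator.

# T-tubule organization

The T-tubule index quantifies the periodic component of pixel variance along
the cell axis. The ROI (or whole image) is averaged across the transverse
direction into a 1D longitudinal profile; the mean is removed; a Hann taper
controls spectral leakage; and the 1D power spectrum is computed. The
spectrum is also reported normalized to its central (lowest non-DC) peak for
comparability across staining intensities, but the scalar index is a pure
ratio and therefore independent of that constant:

$$tt = \frac{\int_{0.3}^{0.7} P(f)\,df}{\int_{f_1}^{f_{Nyq}} P(f)\,df}$$

with trapezoidal areas, the band defaulting to 0.3–0.7 μm⁻¹ around the
~0.5 μm⁻¹ sarcomeric fundamental, and the "entire spectrum" taken from the
first non-DC bin to Nyquist (DC is brightness, not structure). The index lies
in [0, 1] and is invariant to affine intensity rescaling. 1D profiling was
chosen over a full 2D FFT because the band is defined on a scalar spatial
frequency; the transverse average is the matched measurement for transversely
oriented tubules. Because windowing, ROI placement and the 1D reduction are
implementation choices, the absolute index is implementation-scaled: only
within-pipeline comparisons (ordered vs. disarrayed, group contrasts) are
meaningful, which is how it is used and tested.

`orient_roi()` estimates the cell's long axis from intensity-weighted
second-order moments (background suppressed at the median) and rotates the
image (in-package bilinear resampling, so the row/column convention is under
our control) to put the striation-normal direction along the profile axis;
near-isotropic images warn and default to angle 0. Orientation round-trips
within 2° on masked synthetic cells.

# Group statistics

`compare_means()` reports mean ± SE per group and runs the design-appropriate
test: unpaired equal-variance t-test for two groups; one-way ANOVA with
Bonferroni-corrected pairwise post hoc comparisons otherwise (pairwise flags
are *protected*: significant only when the omnibus test is also below α,
mirroring the ANOVA-then-post-hoc procedure and keeping the simulated
family-wise error comfortably under 0.05); and fixed-effects two-way ANOVA
with interaction for factorial designs. Repeated-measures/mixed-effects
extensions are deliberately out of scope; the fixed-effects contract is what
is validated. `compare_proportions()` compares per-cell categorical flags
(cells with DADs, waves, embers) by the classic chi-square test without Yates
correction by default (a `correct` flag is available); on the 2×2 table
[[9,1],[1,9]] it reproduces the hand-computed χ² = 12.8. Bonferroni
adjustment is `min(1, m·p)`.

# Synthetic data: what it emulates, and what it does not

The generators reproduce the *geometry and statistics* of the acquisitions
the analyses target, with every ground-truth quantity computable in closed
form:

* **AP trains** (`gen_ap_train`): 1 Hz pacing (default), 10 kHz sampling,
  piecewise-linear AP template (1 ms rise, 20 ms plateau, linear
  repolarization) whose per-beat APD₉₀ is drawn from N(250, σ) ms, so true
  APD₅₀/APD₉₀ are exact; DADs as 50 ms raised-cosine diastolic humps with
  per-diastole probability; optional Gaussian noise. The template is *not* a
  biophysical ionic model — no currents, no restitution, no drug action.
* **Fluorescence traces** (`gen_ca_trace`): 2 kHz sampling, linear-rise /
  mono-exponential-decay transients (true T₀.₅ = τ ln 2), caffeine pulse as a
  large slow transient, waves as raised cosines, baseline F₀ = 100 with
  background 10. No dye kinetics, no conversion to absolute [Ca²⁺], no
  motion artifacts.
* **Line-scans** (`gen_linescan`): 512×512 xt frames at 2 ms/line (0.5 kHz)
  and 0.15 μm/pixel, sparks as separable Gaussian(space) × linear-rise +
  exponential-decay(time) kernels — the standard simulation model in the
  spark-detection literature, and the model under which FWHM/FDHM/τ are
  defined (true FWHM = 2√(2 ln 2)·σ, true FDHM = rise/2 + τ ln 2). Event
  centers are quantized to the sampling grid so the nominal peak is attained
  at a sample. Default noise 0.1·F₀. Written as 16-bit TIFF (the assumed
  line-scan bit depth); no photon (Poisson) noise, no 2D sparks, no wave-like
  propagating events.
* **Striated cells** (`gen_striation_image`): 1024×1024 px at 78/1024 ≈
  0.076 μm/pixel, Gaussian intensity bands every 2.0 μm (fundamental exactly
  at 0.5 μm⁻¹), 8-bit. Jitter and dropout act *coherently on whole bands* —
  z-lines are displaced or lost as units, the microscopic picture of
  T-tubule disarray. This matters: jitter applied incoherently along a band
  averages into band *widening*, which suppresses harmonics faster than the
  fundamental and can raise a band-ratio index; coherent displacement
  converts order into broadband power and the index falls monotonically with
  both jitter (0 → 1 μm) and dropout (0 → 1), which the tests assert over
  seeds. An optional elliptical cell mask provides the elongated geometry
  needed by the orientation estimator.

All generators consume a single integer seed, restore the caller's RNG state,
and return machine-readable ground truth (`ground_truth()`); identical seeds
give bit-identical outputs. Passing tests on these data demonstrates the
*estimators* are correct under the stated models at realistic noise; it does
not certify performance on real recordings with drift, motion, photobleaching
or non-Gaussian noise, which are outside the simulation's scope.

# Numerical choices and problem sizes

Level crossings are always linearly interpolated; ties in maxima resolve to
the earliest index; exponential fits use log-linear starts and
Levenberg–Marquardt (or a log-linear fit alone for spark decays, which is
deterministic and robust at profile SNR); degenerate inputs (flat traces,
zero-variance images, empty ROIs, non-decaying segments) raise warnings or
errors rather than returning silent values. The test and acceptance workloads
use 10 spark frames of 5 events (50 sparks), 100 null frames for the
false-positive rate, 20 seeds per jitter level for the T-tubule monotonicity
check, and 1000 simulations for the statistical-power and family-wise-error
calibrations — sizes chosen so every stochastic assertion is stable under
seed changes while the full suite runs in about a minute.

# Known limitations

* The AP template's linear repolarization makes APD ground truth exact but
  under-represents the convex late repolarization of real rodent APs; APD
  estimators only see crossing times, so this mainly affects how
  representative the DAD diastole window is.
* Spark parameters assume near-separable events; strongly overlapping sparks
  are merged by the region-growing step and parameterized as one event.
* The amplitude de-attenuation factor assumes a Gaussian spatial profile;
  for grossly non-Gaussian events it reverts toward a small bias rather than
  failing.
* The T-tubule index is implementation-scaled (windowing, 1D reduction, band
  edges); compare values only within this pipeline.
* The mixed-effects variant of the two-way design is not implemented; only
  the fixed-effects contract is tested.
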