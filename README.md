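# cardioquant

Quantification toolkit for cardiotoxicity phenotyping of isolated
cardiomyocytes. Anthracycline (and anti-HER2) cardiotoxicity shows up in
single cells long before pump failure: action potentials lengthen and become
unstable beat to beat, the sarcoplasmic reticulum (SR) leaks Ca²⁺ as sparks
and waves, and the T-tubule lattice loses its ~2 μm periodicity. `cardioquant`
implements the measurements behind each of those readouts as a tested R
package, together with synthetic-data generators whose ground truth is known
in closed form, so every estimator is verifiable end to end.

## What it computes

**Action potentials** (`segment_aps`, `ap_features`, `detect_dads`,
`detect_eads`, `stv`): APD₅₀/APD₉₀ (time from take-off at dV/dt_max to the
interpolated crossing of `peak − x·(peak − E_diast)`), diastolic potential,
upstroke velocity; delayed afterdepolarizations by the ≥ 1 mV diastolic
deflection rule; early afterdepolarizations during repolarization; and
beat-to-beat repolarization variability as the short-term variability

    STV = Σ |APDₙ₊₁ − APDₙ| / (n_beats · √2)

over 30 consecutive beats, with Poincaré pairs (`APDₙ`, `APDₙ₊₁`) returned.

**Ca²⁺ transients** (`normalize_f`, `transient_features`,
`caffeine_analysis`, `detect_resting_events`, `normalize_to_ctrl`): F/F₀
normalization after background subtraction; transient amplitude and
half-decay time T₀.₅ (= τ·ln 2 for mono-exponential decay); SR content from
the caffeine-transient amplitude and NCX function from its mono-exponential
decay constant; resting Ca²⁺ waves by the > 3 SD-over-F_rest rule.

**Ca²⁺ sparks** (`detect_sparks`, `spark_params`, `analyze_sparks`,
`summarize_sparks`): SparkMaster-style deterministic detection on line-scan
(xt) images at criterion 3.8; amplitude (ΔF/F₀), FWHM, FDHM, FW, FD,
time-to-peak and decay τ per spark; spark mass = amplitude · 1.206 · FWHM³;
frequency in events·s⁻¹·(100 μm)⁻¹; SR leak = mean mass × frequency; embers
as sparks with FDHM > 20 ms; in-focus filtering at amplitude > 0.3.

**T-tubule organization** (`tt_power_index`, `orient_roi`): 1D spatial power
spectrum of the longitudinal intensity profile, and the fraction of spectral
power in the 0.3–0.7 μm⁻¹ band around the 0.5 μm⁻¹ sarcomeric fundamental —
an index in [0, 1] that falls with z-line jitter and dropout.

**Group statistics** (`compare_means`, `compare_proportions`): mean ± SE per
group, t-test / one-way ANOVA with Bonferroni-protected post hoc pairs /
two-way ANOVA, and chi-square comparison of per-cell flags (cells with DADs,
waves, embers).

**Synthetic data** (`gen_ap_train`, `gen_ca_trace`, `gen_linescan`,
`gen_striation_image`): paced AP trains with controllable APD statistics and
DADs; stimulated/caffeine/wave fluorescence traces; spark-bearing 512×512 xt
frames at 0.5 kHz; striated 1024×1024 8-bit cell images at 78/1024 μm/px.
All seeded, all returning `ground_truth()`.

I/O: traces as headered delimited text (`read_trace`/`write_trace`), images
as 8/16-bit TIFF (`read_image`/`write_image`, multi-frame stacks concatenate
along time), JSON run manifests (`write_run_manifest`), and a CLI at
`inst/cli/cardioquant.R` with subcommands
`simulate | ap | cat | sparks | tt | report`.

## Worked example

```r
library(cardioquant)

# a 30-beat paced train with 10 ms beat-to-beat APD90 SD and sparse DADs
tr   <- gen_ap_train(ap_train_spec(n_beats = 30, apd90_mean = 250,
                                   apd90_sd = 10, dad_probability = 0.2,
                                   dad_amplitude = 2, noise_sd = 0.2,
                                   seed = 42))
segs <- segment_aps(tr)
head(ap_features_table(segs), 3)
#>   beat take_off_time    apd50    apd90   e_diast dvdt_max     peak
#> 1    1         200.5 153.6887 261.9881 -79.99551 124.5863 40.60519
#> 2    2        1200.6 143.3854 243.5685 -80.00892 124.6872 40.49163
#> 3    3        2200.1 149.2718 253.1748 -79.98986 123.6980 40.44179

stv(ap_features_table(segs)$apd90)
#> <BVRResult> STV 9.681 ms over 30 beats (denominator n*sqrt(2))
nrow(detect_dads(tr, segs))   # 8 events, matching the generator's truth
#> [1] 8

# three sparks on a noisy line-scan, then the derived per-cell indices
sp  <- data.frame(x_um = c(15, 40, 60), t_ms = c(250, 500, 800),
                  amplitude = c(1.2, 0.8, 0.5), sigma_um = c(1.0, 1.2, 0.9),
                  rise_ms = 10, tau_ms = c(30, 25, 35))
img <- gen_linescan(linescan_spec(sparks = sp, noise_sd = 10, seed = 7))
summarize_sparks(analyze_sparks(img))
#> <SparkSummary> 3 spark(s); freq 3.815 /s/100um; mean mass 13.06; leak 49.809; embers 2

# T-tubule regularity of a striated cell with 0.3 um z-line jitter
tt_power_index(gen_striation_image(striation_spec(jitter_sd = 0.3,
                                                  noise_sd = 8, seed = 1)))
#> <TTPowerResult> tt_index 0.7752 in band [0.30, 0.70] um^-1; peak at 0.500 um^-1
```

The STV of 9.7 ms reflects the injected 10 ms beat-to-beat APD variability
(for i.i.d. Gaussian APDs with SD σ the expected STV is `2σ/√π/√2 ≈ 0.8·σ`,
here ≈ 8 ms, plus measurement noise); all three sparks are recovered with their kinetics, two qualify as
embers (FDHM > 20 ms); and the T-tubule spectrum peaks exactly at the
0.5 μm⁻¹ fundamental with most band power retained at moderate jitter.

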