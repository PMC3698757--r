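---
title: "Circadian blood-pressure telemetry: models, methods, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian blood-pressure telemetry: models, methods, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telemetrybp)
```

## What this package computes

Radiotelemetry in freely moving rats yields a continuous arterial-pressure
waveform across the light/dark cycle. From that single signal,
cardiovascular phenotyping studies routinely derive four families of
quantities, and `telemetrybp` implements the full chain:

1. **Beats** — systolic peak detection turns the waveform into a per-beat
   series of systolic (SBP), diastolic (DBP) and mean arterial pressure
   (MAP, the time-average over the beat) plus the pulse interval (PI, ms).
2. **Circadian summaries** — telemetry-cadence binning (30-s averages every
   5 min), 12-hour dark/light means anchored at dark onset, and the
   dipper/nondipper classification of the daily blood-pressure rhythm.
3. **Spectra** — Welch power spectral density of the beat-to-beat SBP
   series, integrated over the low-frequency band (0.27–0.75 Hz, the rat
   Mayer-wave band; an index of vasomotor sympathetic tone) and the
   high-frequency band (0.75–3.3 Hz, respiratory).
4. **Spontaneous baroreflex gain (sBRG)** — the sequence method: maximal
   runs of concordant spontaneous SBP and PI ramps, per-run least-squares
   slope of PI on SBP (ms/mmHg), averaging **positive slopes only**, since
   negative slopes reflect non-baroreflex coupling.

A fifth module implements the statistical decision tree such studies apply
to grouped summaries: Shapiro–Wilk normality per group and Bartlett variance
homogeneity route the data either to factorial ANOVA (with repeated-measure
error strata where appropriate, Tukey or Bonferroni-t post hoc) or to
Kruskal–Wallis with the Steel–Dwass all-pairs post hoc.

Because no public dataset accompanies this class of experiment, the package
ships a seeded synthetic-waveform generator whose ground truth is known
exactly; every stage of the analysis is validated by parameter recovery
against it.

## The generator

### Beat-domain model

The generator is beat-based. Beat $i$ has a peak (systolic) time $T_i$, and

$$\mathrm{SBP}_i = m(T_i) + \tfrac{PP}{2} + \underbrace{a_{LF}(T_i)\sin(2\pi f_{LF} T_i) + a_{HF}\sin(2\pi f_{HF} T_i) + \varepsilon_i + w_i}_{\text{excursion } x_i},$$

$$\mathrm{PI}_i = \frac{60000}{\mathrm{HR}(T_i)} + G\,x_{i-d} + \eta_i, \qquad T_{i+1} = T_i + \mathrm{PI}_i/1000 .$$

* $m(t)$ is the slow MAP setpoint: the strain's dark/light levels joined by
  half-cosine ramps over 30 min at each light transition (a step would be a
  spectral artifact), plus any drug effect.
* $w_i$ is activity-linked wander: a unit-variance AR(1) over beats with a
  ~2-min correlation time, scaled by `activity_gain` (0.4 mmHg per activity
  count) times the period's activity level. It models slow behavioral BP
  fluctuation.
* $\varepsilon_i$ is white SBP noise (`noise_sd`), $\eta_i$ white PI noise
  (`pi_noise_sd`, the non-baroreflex PI variability).
* $G$ is the baroreflex coupling gain `brg_true` (ms/mmHg, positive:
  higher pressure lengthens the interval — reflex bradycardia), with an
  optional delay $d$ in beats (default 0). The reflex sees the **full**
  excursion $x$ from the slow setpoint, including the wander, so the
  coupling recovered by the sequence method equals $G$ by construction.

Because $T_{i+1}$ depends on $\mathrm{PI}_i$ which depends on the sinusoid
phases at $T_i$, beat times are generated by an exact sequential kernel
(compiled); slowly varying profiles are passed as 5-s lookup grids. The
stream is a deterministic function of the seed.

### Waveform rendering

The continuous trace is rendered peak-aligned: between the troughs
(midpoints of successive peaks) the pressure follows
$m_i + A_i\cos(\pi (t-T_i)/h)$ with the appropriate half-width $h$ on each
side. Three properties make the ground truth closed-form: the peak value is
exactly $\mathrm{SBP}_i$, the peak-to-peak interval exactly
$\mathrm{PI}_i$, and the within-beat time average exactly $m_i$ (each
half-cosine integrates to zero). The default sampling rate is 250 Hz — of
the order of implanted-telemetry acquisition — which keeps the detector's
quadratic-interpolation timing error well below 0.1 ms.

### Strain presets

The three built-in presets carry the published 12-h baseline dark/light MAP
means that define the strains' phenotypes: WKY 102.1/94.4 mmHg (dipper
normotensive), SHR 142.0/134.8 (dipper hypertensive), SHRcp 133.4/131.7
(nondipper hypertensive — a 1.7-mmHg dip). **Everything else is a
documented non-published default**: heart rates (330/300, 320/290, 310/285
beats/min dark/light; slightly lower in SHR/SHRcp than WKY, matching the
reported ordering), pulse pressures (35–45 mmHg), oscillation amplitudes
(LF 2–2.5 mmHg dark, lower in the light period for the dipper strains and
nearly flat for SHRcp; HF 1 mmHg at 1.5 Hz ≈ 90 breaths/min), baroreflex
gains (1.2 / 0.8 / 0.6 ms/mmHg, SHRcp lowest) and noise levels (SBP 1 mmHg,
PI 1 ms). Directions follow the reported strain contrasts; magnitudes are
plausible for rat telemetry and are exposed for override via
`register_strain_preset()`.

### Cohorts and between-animal jitter

`simulate_cohort()` derives per-animal seeds from the master seed
(counter-based, order-independent) and draws per-animal deviations around
the preset: a *level* shift common to both periods (SD 2 mmHg), a
*circadian-dip* deviation split $+D/2$ dark / $-D/2$ light (SD 3 mmHg), and
small HR/gain/LF jitters. Two deliberate design choices:

* **Draws are centred within the cohort** (sum to zero). The preset states
  the *group* mean; centring makes the simulated group mean equal it
  exactly while preserving between-animal spread. This is a standard
  conditioning/variance-reduction device; uncentred draws can be requested
  (`cohort_jitter(centered = FALSE)`).
* With level SD 2 and dip SD 3 at $n=5$, the realized group SEM of a
  period mean is ≈ 1 mmHg and per-animal dark-light differences have SD
  ≈ 3 mmHg — the order of spread visible in published baseline telemetry
  tables at this group size, and wide enough that a 1.7-mmHg dip is usually
  *not* statistically detectable in a 5-animal paired test while 7–8-mmHg
  dips are. That is precisely the nondipper/dipper contrast the
  classification module must reproduce.

### Drug schedules

`drug_schedule()` models once-daily dosing at dark onset with weekly
escalation (default 0.1 → 0.3 → 1.0 mg/kg). Effects are sustained from each
dose to the next (an exponential-decay mode exists but is off by default,
since the emulated compound's effect persists through both periods). The
default MAP effects (−2/−6/−15 mmHg at the three doses, both periods) are
generator free parameters chosen to be monotone in dose; the analysis-side
`dose_response()` summarizer recovers whatever is injected, which is what
the tests check.

## Analysis choices worth knowing

**Beat detector.** Local-maximum search with a refractory window of
`60000/max_hr` ms and a unit-free prominence threshold (0.25 × median
peak-to-trough excursion of a calibration pass). Peak time/height are
refined by three-point quadratic interpolation, giving sub-millisecond PI
resolution at 250 Hz. Beats with intervals outside [`60000/max_hr`,
`60000/min_hr`] (defaults 200–500 beats/min) are excluded as artifacts, not
interpolated, and counted. Per-beat MAP is the sample time-average between
successive peaks; per-beat MAP therefore carries a small zero-mean sampling
quantization (a few tenths of a mmHg per beat at 250 Hz) that vanishes in
any averaged quantity.

**Telemetry cadence.** Bins are 5 min, each valued from its first 30 s
(≥ 3 beats required), reproducing the standard acquisition scheme; hourly
LF and sBRG values use one 5-min analysis window at the top of each hour
(configurable offset). Invalid windows propagate as missing, never zero.

**Spectra.** Beat-to-beat SBP is linearly interpolated to 10 Hz (above
2 × 3.3 Hz with margin). Welch: 60-s segments, 50% overlap, periodic Hann
taper, per-segment mean and linear-trend removal, one-sided density
normalized so the spectral integral matches the series variance (Parseval).
Band integrals are trapezoids with interpolated band edges, making band
additivity exact. Segment length, overlap, taper and interpolation rate are
not specified by the emulated acquisition systems, so all are exposed
configuration with these defaults.

**Sequence method.** Defaults `min_len` 3 beats, `min_dsbp` 0.5 mmHg,
`min_dpi` 1 ms, `delay` 0, `min_r` 0.8 — conventional settings; the
literature's "modified" variants differ in unpublished details, so no
fidelity to a specific implementation is claimed and everything is
configurable. Down-ramps (falling SBP with shortening PI) are *included*:
they yield positive slopes, and only the slope sign is an exclusion
criterion. The estimator has a known **upward selection bias when the
non-reflex PI noise is comparable to the reflex-coupled per-beat PI
changes** (sequence inclusion then conditions on favorable noise): at the
strain presets' PI noise of 1 ms the hourly estimate at a true gain of
1.2 ms/mmHg runs roughly 15–20% high, and proportionally worse at very low
gains. In the noise-free limit the estimate converges to the injected gain
(the remaining ~1% reflects detector timing quantization). Gain-recovery
validation therefore uses a dedicated fixture (`lf_amp` 3, `hf_amp` 2,
`noise_sd` 1, `pi_noise_sd` 0.5 ms) in which inclusion thresholds are met
by the coupled signal itself across the tested gain ladder
{0.5, 1, 2, 4} ms/mmHg.

**Dipper classification.** A *statistical* definition, matching how such
studies state their conclusions, not the clinical 10%-dip rule: the record
is a dipper iff the light-period MAP mean is significantly lower than the
dark-period mean in a paired comparison (paired t when Shapiro–Wilk accepts
normality of the differences, Wilcoxon signed-rank otherwise) at α = 0.05.
Pairs are animals (single-day cohort) or days (multi-day single animal).
The descriptive dip percentage is reported either way. Note the n = 5
signed-rank test cannot reach p < 0.05, so Shapiro–Wilk rejections at that
size are conservative for dipper calls.

**Decision tree.** Route parametric only when every group passes
Shapiro–Wilk and Bartlett accepts homogeneity at α = 0.05; degenerate
(zero-variance or undersized) groups route nonparametric with the reason
recorded. Repeated measures use classical within-subject error strata
(`aov` with `Error(subject/within)`), not mixed models, matching the named
methodology; for a single within factor the Greenhouse–Geisser ε is
estimated and corrected p-values reported alongside (sphericity handling is
unstated in the emulated methodology, so this is a documented choice, not a
fidelity claim). Post hoc families: Tukey HSD over the cell crossing for
1–2 factor designs; Bonferroni-corrected pairwise t for 3-factor designs.
Steel–Dwass is the Steel–Dwass–Critchlow–Fligner form: pairwise Wilcoxon
rank sums standardized with tie correction and referred to the Studentized
range with infinite error df.

## What the validation shows — and what it cannot

The test suite regenerates all its data. Problem sizes were chosen to give
stable Monte-Carlo estimates at interactive runtimes: 24-h, 5-animal
cohorts at 250 Hz for end-to-end mean recovery (≈ half a million beats per
animal); 20 seeded cohort replicates per strain for dipper-call rates
(beat-domain, the waveform/detector stage being validated separately);
6-h recordings for spectral recovery; 1-h recordings × 10–20 seeds per
rung for the gain ladder; 1000 null replicates for the decision-tree
type-I rate; 100 random 500-beat series for the brute-force sequence
oracle.

The generator reproduces the statistical *structure* the analysis assumes —
pulsatility, circadian levels, band-limited oscillations, baroreflex
coupling, between-animal spread. It does **not** emulate real waveform
morphology (dicrotic notch, movement artifacts, signal dropout), real
activity bursts (episodic rather than AR(1)), non-stationary oscillation
amplitudes, or pharmacokinetics (drug effects are step functions of the
dosing calendar). Passing recovery tests therefore demonstrates the
correctness of the computations under the stated model, not detector
robustness to pathological clinical-grade artifacts.

## Reproducing the headline calibration

`scripts/acceptance.R --seed 42 --out results/acceptance.json` re-runs the
full simulate → detect → bin → summarize chain for the three strain cohorts
and writes the five 12-h group MAP means (WKY dark/light, SHR dark, SHRcp
dark/light) as JSON; see the README for the exact invocation and the
interpretation of each value.
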