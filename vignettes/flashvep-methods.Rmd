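---
title: "Methods: flash-VEP waveform analysis with flashvep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flash-VEP waveform analysis with flashvep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashvep)
```

## The problem

Flash visual evoked potentials (VEPs) recorded over the rodent visual
cortex summarize conduction through the whole visual pathway in a single
averaged waveform with three canonical deflections: a first positive peak
(P1), a first negative peak (N1) and a second positive peak (P2) before
the trace's sustained late negativity. N1 latency indexes conduction from
the retina to primary visual cortex; P2 and the inter-peak ("implicit")
times P1-N1, N1-P2 and P1-P2 probe intracortical transmission beyond V1.
In demyelinating-disease models (experimental autoimmune
encephalomyelitis, EAE), latency delays of these components track disease
and treatment (for example transcranial direct current stimulation)
longitudinally, expressed per eye as percent change from each eye's own
baseline session.

`flashvep` implements this analysis end to end: epoched sweep handling,
block and grand averaging, zero-phase filtering, automated ordinal
marking of P1/N1/P2, implicit times, percent-change endpoints,
eye-level stratification by early latency delay, and the nonparametric
comparison battery. Because raw recordings of this kind are rarely
deposited, the package includes a first-class synthetic-cohort generator
with known ground truth, so every stage is testable.

## The waveform and acquisition model

One epoch is 500 ms of single-channel EEG from flash onset, sampled at
4096 Hz (2048 samples). A session records 3 averages of 20 sweeps (60
epochs); flashes are delivered at 1 Hz. These acquisition defaults are
the package's study conditions (`acquisition_spec()`).

The simulator renders each component as a Gaussian bump
$a \exp\{-(t-\ell)^2 / 2\sigma^2\}$ with peak latency $\ell$, signed
amplitude $a$ and $\sigma$ set from the half-width at half maximum. A
Gaussian is unimodal and differentiable and places its peak exactly,
which is what latency-recovery testing needs; it does not claim to be a
biophysical model of the cortical generator. The peak is snapped to the
nearest sample so the rendered extremum equals the nominal amplitude
exactly.

Default component truth is P1 at 25 ms (+10 µV, width 5 ms), N1 at 50 ms
(−15 µV, width 8 ms), P2 at 90 ms (+12 µV, width 12 ms). The latencies
are conventional placeholders for mouse flash VEP — no population
reference values exist for this preparation — and the amplitudes and
widths were chosen once as realistic for epidermal rodent recordings.
All are configurable; none were revisited after tests were written.

Background noise is Gaussian $1/f^\alpha$ ("pink") noise, default
$\alpha = 1$ and SD 5 µV per sweep, generated by spectral shaping in the
Fourier domain; an optional 50 Hz sinusoid with per-sweep random phase
models powerline pickup, and per-sweep latency jitter (default SD 1 ms)
models trial-to-trial variability that the averaging stage must absorb.
What the generator does *not* emulate: non-stationary artifacts
(movement, electrode drift), amplitude variability across sweeps,
inter-eye correlation within a mouse, and any amplitude effect of
disease. Passing tests on synthetic cohorts therefore demonstrate the
*pipeline's* correctness under controlled conditions, not robustness to
every failure mode of real recordings.

Longitudinal cohorts (`cohort_design()`, `simulate_cohort()`) assign each
group a latency-delay trajectory: percent delay per component as a
function of day, zero at baseline by construction, applied
multiplicatively to the baseline latencies. Treatment arms are modeled
purely as trajectory modifiers. Dropout is representable as per-eye
right-censoring. All randomness derives from a single design seed through
fixed per-session sub-seeds, so cohorts are bit-reproducible and sessions
can be regenerated on demand without holding all epochs in memory.

## Preprocessing

The analysis band is 5–100 Hz with an optional 50 Hz notch. Filters are
applied forward-backward (zero-phase) with reflection padding, because
the package's endpoint is latency: any causal filter would bias it. The
bandpass is a 4th-order Butterworth high-pass and low-pass pair; the
notch is a 2nd-order IIR biquad with Q = 30.

Two numerical points deserve explanation:

* **Notch gating.** Any notch removes the evoked response's own energy
  at 50 Hz, and the resulting ripple (period 20 ms) measurably moves the
  near-flat top of the slow P2 component — by 2–3 samples at 4096 Hz,
  regardless of how narrow the notch is made. The notch is therefore
  gated (`notch_mode = "auto"`): it engages only when a spectral ratio
  test finds narrowband power at the line frequency well above the
  neighbouring bands. Clean traces keep sample-exact latencies;
  contaminated traces are cleaned. `"on"` and `"off"` override the gate.
* **Stationary line removal.** When the notch engages, the least-squares
  sine/cosine fit at the line frequency is subtracted before filtering.
  A forward-backward IIR notch alone leaves phase-dependent edge ringing
  on short epochs (reflection padding continues a sinusoid smoothly only
  at a zero crossing); the regression removes a stationary tone of any
  phase exactly, and the IIR notch then absorbs residual drifting
  interference.

Averaging is the pointwise mean per 20-sweep block; the grand average is
the sweep-weighted mean of blocks. Marking is performed on the grand
average by default (the three block averages feed a cross-block
reproducibility check, `mark_reproducibility()`), since with 3 × 20
sweeps the grand average has the best signal-to-noise ratio and the
original recording protocol does not dictate which trace is marked.
Filtering commutes with averaging (both linear), so the pipeline filters
the averages rather than each sweep.

## Component detection

`detect_components()` automates the ordinal definitions: P1 is the first
positive local peak in its search window, N1 the first negative local
trough after P1, and P2 the first subsequent positive local peak before
the "complete hyperpolarization" — the sustained late negativity of the
trace. Operational choices, all configurable via `search_windows()`:

* Default windows P1 ∈ [10, 45] ms, N1 ∈ [25, 80] ms (after P1),
  P2 ∈ [45, 150] ms (after N1); the first 10 ms are blanked for the
  stimulus artifact. These are analysis settings, not physiological
  constants.
* Candidate peaks are screened on a 1.2 ms moving-average smoothed copy
  of the trace and must exceed 1 µV in absolute amplitude, so
  single-sample spikes and sub-microvolt residual-noise ripples are
  never marked as the "first" peak — this mimics what a human marker
  implicitly ignores. The reported latency is always read from the
  unsmoothed trace at the nearest raw extremum.
* The hyperpolarization bound is the onset of the first excursion after
  60 ms in which the trace stays at or below zero for at least 40 ms,
  with a hard cap at 150 ms.
* Ties (flat-topped peaks) resolve to the earliest sample, preserving
  "first peak" semantics.
* Amplitudes are peak-to-baseline with the baseline taken over the
  blanking interval; N1-P2 amplitude is peak-to-peak. A polarity flag
  accommodates recordings referenced the opposite way.

Absent components are flagged (`"absent"`, or `"no_signal"` for a flat
trace), never fabricated; a missing P1 still allows N1 and P2 to be
reported. Implicit times are exact latency differences and inherit
absence. The emitted marks always satisfy P1 < N1 < P2 and
(P1-N1) + (N1-P2) = (P1-P2) exactly.

The test suite holds the detector to a brute-force oracle — enumerate
every raw local extremum by sign and take the first satisfying each
ordinal definition — on randomized smooth multi-bump fixtures, exactly.

## Endpoints and stratification

Each measure (P1, N1, P2 latencies and the three implicit times) is
converted to percent change from the same eye's baseline (day 0)
session: $100 (x_t - x_0)/x_0$. Baseline percent change is exactly zero;
eyes without a baseline for a measure contribute no endpoint for it
(no imputation). Eyes, not mice, are the analysis unit.

EAE eyes are stratified into "with latency delay" (W LD) and "without
latency delay" (W/O LD) strata by whether the N1 percent change at the
early timepoint (default 7 days post-immunization) exceeds a threshold.
The original stratification was a judgment call without a stated
criterion; the package's reproducible surrogate is Healthy mean + 2 SD
of the same endpoint, derived from the cohort's Healthy eyes, with an
absolute percent threshold as an override. Eyes missing the rule
timepoint are `"unclassifiable"` and excluded from stratified
comparisons. `pool_eae()` collapses all EAE eyes for pooled contrasts.

## Statistics

The battery (`run_endpoint_battery()`) runs, per measure × timepoint:

1. a D'Agostino–Pearson omnibus normality screen per group (recorded;
   groups under n = 8 are screened as NA). The omnibus statistic
   $K^2 = Z_1^2(\sqrt{b_1}) + Z_2^2(b_2)$ uses D'Agostino's skewness
   transformation and the Anscombe–Glynn kurtosis transformation,
   referred to $\chi^2_2$. It is implemented in the package and verified
   against an independent implementation.
2. the nonparametric branch: tie-corrected Kruskal–Wallis H (via
   `stats::kruskal.test`) followed by Dunn's post-hoc z tests on pooled
   mid-ranks with tie-corrected variance, Bonferroni-adjusted over the
   requested comparison family (all pairs by default; the family is
   explicit because the original analysis software does not state it).
   The nonparametric branch is always taken; longitudinal mixed-effects
   modeling is deliberately out of scope, and per-timepoint tests
   reproduce figure-level significance structure.

The paired N1-versus-P2 contrast (`n1_p2_contrast()`) is a two-sided
paired Student t on per-eye (P2 − N1) percent-change differences, used
on pooled EAE eyes at early timepoints. Degenerate all-zero differences
return t = 0, p = 1; a nonzero constant difference has no finite t and
errors. Significance stars follow the convention \*, \*\*, \*\*\*,
\*\*\*\* for p < 0.05, 0.01, 0.001, 0.0001; α = 0.05 throughout.

## Verification scale and reproducibility

The shipped tests and `scripts/acceptance.R` verify, among other
properties: latency recovery over 200 simulated sessions at background
SD = |N1|/5 (median absolute error and bias per component), the
$1/\sqrt{20}$ averaging gain over 1000 replicates, filter latency
neutrality on noise-free sessions and ≥ 20 dB tone suppression,
Kruskal–Wallis type-I calibration over 2000 null replicates, paired-t
power at d = 1 with 40 eyes over 1000 replicates, ≥ 90% stratification
label recovery, and qualitative reproduction of the published
significance pattern on two synthetic cohorts (disease course at 7 dpi
with arm sizes 16/24/16 eyes; stimulation arms at 8 dpi with
16/34/30/28 eyes). These problem sizes were chosen as the package's
standard verification scale. Note that two-timepoint designs are used
for the pattern checks because only the early timepoint carries the
asserted contrasts.

## Known limitations

* The trace I/O layer supports the package's documented tabular CSV
  format; EDF(+) import/export is not implemented.
* Latencies are reported on the sample grid (no sub-sample
  interpolation), matching visual-marking practice; at 4096 Hz the
  quantization is 0.244 ms.
* The stratification threshold is a reproducible surrogate for an
  unstated human criterion; absolute-threshold overrides should be used
  when comparing against analyses that used a different rule.
* Statistical results on simulated cohorts reproduce qualitative
  significance structure, not the published p-values, which depend on
  unreleased raw recordings.
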