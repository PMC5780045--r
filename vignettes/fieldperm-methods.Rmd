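---
title: "fieldperm: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fieldperm: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fieldperm` analyses event-related intracranial electrophysiology of the
kind recorded intraoperatively during deep-brain-stimulation surgery:
subthalamic nucleus (STN) local field potentials from macroelectrodes,
intracranial EEG from subdural strips over prefrontal cortex (PFC), and
spike trains from STN microelectrodes, all aligned to a rapid trial
structure (a stimulus every ~1 s, blocks of eight stimuli of which four are
to-be-encoded targets and four to-be-ignored distractors). Because real
recordings of this kind are scarce and access-restricted, the package pairs
the analysis chain with a synthetic-session generator whose ground truth is
known exactly, so that every statistical claim the chain can make is
testable as a recovery or calibration experiment.

This vignette documents the model assumptions, the tunable parameters and
their defaults, what the generator does and does not emulate, the numerical
choices, and the open design decisions we fixed.

## 1. The analysis chain

**Preprocessing.** Signals are bandpass filtered 1–500 Hz with a 60 Hz
notch and resampled to 1 kHz. Filtering is zero-phase by construction: the
transfer function (raised-cosine transition bands, hard spectral notch) is
applied in the frequency domain, so event latencies are never shifted, and
Fourier resampling handles non-integer rate ratios (1502.4 Hz to 1 kHz)
exactly. STN macroelectrodes are re-referenced to their common average;
strip contacts are re-referenced bipolarly (n contacts yield n−1 channels).
Epochs span −250..1250 ms around each stimulus with 1000 ms buffers of real
data on each side; buffers survive the spectral transform and are cropped
afterwards. Artifact rejection is automatic here (peak amplitude beyond 6
robust SDs of the per-channel trial-peak distribution, flag-only) where the
original workflow was manual; the threshold is a config parameter and every
decision is logged.

**Spectral decomposition.** Complex Morlet wavelets, wavenumber 6, on a
logarithmic grid `f_k = 2 * 2^(k/8)` Hz, k = 0..46 (47 wavelets, 2 to
~107.6 Hz; we take the conventional "107 Hz" top frequency to be this
rounded grid value). Power is the squared coefficient magnitude; normalized
power is the percent change against the mean power in the 500 ms before
stimulus onset. Two baseline readings are implemented:

* `per_trial = TRUE` (default): each trial is normalized by its own
  pre-stimulus window — the literal per-trial reading of a baseline
  defined relative to each stimulus, used for the event-related
  desynchronization (ERD) and condition-contrast analyses;
* `per_trial = FALSE`: one pooled baseline per channel and frequency,
  used for the within-block decline analyses (section 4).

The Morlet amplitude normalization is chosen so a unit sinusoid at a grid
frequency yields unit coefficient magnitude; nothing downstream depends on
this scale because every analysis is baseline-normalized (normalization is
exactly invariant to rescaling the raw signal).

**Permutation statistics.** All tests share one construction. Each *unit*
(an experimental session for across-session tests, a trial for
within-session tests) contributes a difference map (frequency x time, band
x time, or frequency only). The observed statistic is the mean map across
units. Surrogates either flip each unit's sign independently
(vs-baseline), or permute condition labels (paired swap per unit at the
session level, pooled shuffle at the trial level). Per point,
`z = (observed − surrogate mean) / surrogate SD` and the p-value is the
two-sided normal CDF of z — the construction the reference protocol prescribes —
with an empirical rank p available as an option. Multiple comparisons are
handled by exceedance-mass cluster correction: points with p < 0.05 form
4-connected clusters (runs, in 1D), separately for positive and negative z;
each cluster's mass is the sum of its z values; the null is the
per-permutation maximum absolute cluster mass (per-sign maxima pooled by
absolute value — the reference protocol is silent on this; pooling is the conservative
symmetric choice); corrected p is the +1-smoothed exceedance fraction.
`n_perm` defaults to 200, the reference protocol's value; calibration experiments in
the test suite use the same 200 so they measure the procedure as deployed.

**Connectivity.** For a channel pair, the cross-spectrum at each
time-frequency point is the product of one channel's coefficient with the
other's conjugate. Windowed coherence is the magnitude of the 250 ms
window-averaged cross-spectrum divided by the *square root* of the product
of the window-averaged autospectra. Dividing by the bare product of the
autospectra (the reference protocol's literal description) would not be
bounded by one; the square-root denominator is the standard
magnitude-coherence estimator and guarantees values in [0, 1] — this
deviation is deliberate and prominent. Phase synchrony applies the
identical windowing to the unit-magnitude cross-spectrum (a within-trial
phase-locking value), isolating phase consistency from amplitude; power
correlation is the across-trial Spearman correlation of 250 ms-smoothed
power at each point. Coherence is normalized against a pooled
(per-pair-and-frequency) baseline, then condition means are contrasted
across sessions with the same paired permutation machinery
(normalize-then-average; the reference protocol is ambiguous on the order). Mirroring
the original electrode-selection step, the pipeline feeds the group
contrast only from cortical contacts that show a significant trial-level
condition difference in beta power within their session
(`connectivity$select_contacts`, on by default; switch off for
sensitivity analysis — selection on an independent criterion does not bias
the subsequent contrast but does change its n).

**Spiking.** 1500 ms of spikes per trial (−500..1000 ms); trials with raw
mean rate beyond 10 SD of the across-trial mean are excluded. Continuous
rates are spike trains in 1 ms bins smoothed with a 50 ms-SD Gaussian
kernel, truncated at ±4 SD with each spike's truncated kernel renormalized
to unit in-window mass, so the time integral of each trial's rate equals
its spike count *exactly* (an invariant the tests assert at float
tolerance). The price of exact conservation is a known negative bias of
the rate estimate in the outermost ~2 kernel SDs of the window (mass is
pulled inward); analyses that care about edges should crop them. Rates are
z-scored per trial against the 500 ms baseline and averaged; rate tests
reuse the permutation machinery (trials as units within a cluster, clusters
as units for the population).

**Spike-phase locking.** For each neuronal cluster, the instantaneous
phase of the paired macroelectrode at every spike time (nearest-millisecond
lookup; the reference protocol states no interpolation) over 0..1000 ms, pooled across
trials, gives the mean vector length r per frequency. The surrogate
reassigns each spike the phase from the same time point in a uniformly
drawn *different* trial (with replacement, own trial excluded), 200 times;
`R = (r − mean surrogate r) / SD surrogate r`. Population inference is a
sign-flip test of R across clusters with 1D frequency clustering. A mean
vector length computed across all trials is read here as pooling the
spikes before computing one vector (the alternative — averaging per-trial
r — is available as an option but is biased upward at low spike counts).

## 2. The synthetic world

`ground_truth()` fixes the generative parameters; defaults are the
package's stated world. The source describes its effects qualitatively, so
effect sizes were chosen once, to give comfortable statistical power at
roughly 90 trials per condition, and are not revisited:

| parameter | default | meaning |
|---|---|---|
| `beta_freq` | 20 Hz | beta oscillator frequency |
| `beta_amp`, `theta_amp`, `noise_sd` | 1, 0.6, 1 | component amplitudes (a.u.) |
| `noise_exponent` | 1 | 1/f slope of background noise |
| `erd_depth_*` | 0.35 | fractional beta *amplitude* drop (power drop `(1-d)^2-1` ≈ −58%) |
| `rebound_latency_target` | 700 ms | beta envelope back at baseline |
| `rebound_latency_distractor` | 500 ms | earlier recovery = the condition effect |
| `rebound_ramp` | 300 ms | length of the cosine recovery ramp ending at the latency |
| `theta_gain` | 0.3 | fractional theta increase during the trial |
| `block_slope` | 0.03 | per-position decline of task-window beta amplitude |
| `coupling_strength` | 0.6 | shared-beta mixing weight into the cortical channel |
| `coupling_phase_lag` | π/4 | cortical lag of the shared source |
| `coupling_gain_distractor` | 0.25 | extra coupling during distractor trials |
| `spike_base_rate` | 36 sp/s | matches the reported ~35.9 sp/s cluster average |
| `spike_rate_modulation` | −0.3 | fractional rate change in the trial epoch |
| `kappa`, `preferred_phase` | 1, π | von Mises spike-phase concentration / angle |

Each channel is 1/f-coloured noise plus theta and beta oscillators. The
ERD is a transient envelope dip: a 100 ms attack to `1 − depth`, a hold,
and a `rebound_ramp` cosine recovery completing at the rebound latency —
the attack–hold–recover shape real event-related desynchronization shows.
The condition effect is implemented as a rebound-*latency* difference
(distractor earlier), matching the described early termination of the beta
decrease; a depth difference is available as a secondary knob. Error trials
are targets assigned distractor physiology (`error_fraction`).

**Timing matters.** Stimuli are ~1 s apart, so the 500 ms "baseline" of
each trial lies inside the previous trial's epoch — in the real task as in
the simulation. Any suppression extending past ~500 ms post-stimulus
therefore leaks into the next trial's baseline and biases its normalized
power upward; with the default latencies this residual appears as a mild
(~10%) late-trial positive deflection, a rebound-overshoot look-alike that
real data of this design also show. Consequently (a) within-trial effects
(theta gain, rate modulation, coupling gain, block-slope scaling) use a
transient 0–800 ms raised-cosine plateau and the target ERD has fully
recovered by 700 ms; (b) the within-block beta
decline scales only the task-window amplitude and its analyses use the
pooled baseline: with per-trial baselines, a decline present in baseline
and task alike cancels exactly (we verified empirically that the per-trial
reading even inverts the regression sign), so the ambiguous baseline
wording of the reference protocol is resolved per analysis — per-trial for ERD and
condition contrasts, pooled for the trial-number regression and
repeated-measures ANOVA.

Spikes are an inhomogeneous Poisson process (thinning) with intensity
`r(t) · exp(kappa·cos(phi(t) − phi0)) / I0(kappa)`; the Bessel
normalization keeps the phase factor mean-one under uniform phase so the
base rate is interpretable regardless of locking strength.

**What the generator does not emulate:** volume conduction and electrode
geometry, non-stationary artifacts (rejection is exercised by injected
spikes, not realistic artifacts), reaction times and vocal responses,
Parkinsonian pathophysiology, spike waveforms and sorting errors, and any
anatomical (depth/location) structure. A green recovery test therefore
establishes that the statistics detect the stated effect under the stated
noise model — not that the chain is robust to everything real data do.

## 3. Calibration and recovery experiments

`R/calibration.R` holds the experiments the acceptance report and the test
suite share. The family-wise-error experiment runs 200 independent
repetitions of: 20 null sessions (identical generative law for both
conditions, ~92 trials each), per-session condition-mean normalized-power
maps, paired label permutation with cluster correction; the fraction of
repetitions with any significant cluster estimates the FWE (nominal 0.05,
acceptance bound 0.075). Recovery experiments inject a −30% beta power
drop (trial-level test, overlap of the significant negative cluster with
the injected region), the earlier distractor rebound (session-level
band-limited contrast), and kappa = 1 spike-field locking (population R
spectrum).

These experiments run at 250 Hz with a reduced 12-wavelet bank (6–40 Hz, 4
scales/octave) and stat maps decimated to 20 ms — pure compute scalings:
the exchangeability argument behind the permutation null, and hence the
FWE and recovery properties, do not depend on sampling rate or map
resolution. Sessions use 23 blocks (92 trials/condition) because the
8-trial block generator cannot produce exactly 90.

## 4. Numerical choices and edge cases

* **Convolution** is frequency-domain over the buffered window; analysis
  samples are never zero-padding-adjacent for kernels that fit the buffer.
  At 2 Hz the wavenumber-6 kernel (4σ ≈ 1.9 s) outgrows a 1 s buffer;
  growing the buffer to 2 s changes −250..1250 ms power by ~0.5% at the
  median and ~2% in the mean (worst at the window edges). The tests pin
  this down; analyses at 2 Hz simply inherit the reference protocol's buffer choice.
* **Kernel spectra are cached** per (pad length, rate, bank) — calibration
  transforms thousands of identically shaped sessions.
* **Degenerate inputs**: zero baseline power or coherence is an error (the
  percent change is undefined); zero-magnitude coefficients get phase 0 and
  are counted; silent-baseline trials are excluded from rate averages with
  a flag; constant-across-trials power points are NA in the Spearman map;
  constant sessions are excluded (with warning) from the trial-number
  regression; an all-constant ANOVA input warns and returns NA.
* **Exact identities asserted in tests**: common-average group mean ≡ 0;
  epochs are bit-exact copies of the recording; coherence of a channel
  with itself ≡ 1; rate integral ≡ spike count; permutation p within 0.02
  of exhaustive sign enumeration at 8 units.
* **Sidedness**: pointwise thresholds are two-sided with sign-segregated
  clusters, since both increases (theta) and decreases (beta) are real
  effects in this design.
* **Seeds**: every stochastic function takes a seed; the pipeline fans a
  single top-level seed into per-stage, per-session substreams
  (`derive_seed`), so stages can be rerun independently and a report is
  reproducible bit-for-bit.

## 5. Known limitations

* The independence-of-windows assumption behind the coherence bias oracle
  treats coefficients as Gaussian; heavy-tailed amplitude distributions
  would shift the small-sample bias slightly.
* Trial-level and session-level tests share the normal-CDF-of-z p-value
  construction; with very few units (< 4) the attainable z saturates below
  the 1.96 threshold and nothing can reach significance — a property of
  the z-based construction itself, visible in tiny demo configurations.
* The HDF5 interchange format such toolchains typically use is replaced by
  RDS + TSV + JSON (no R HDF5 bindings in the supported environment).
* The truncated-kernel rate estimator is biased low within ~2 kernel SDs
  of the window edges (the cost of exact count conservation).
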