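---
title: "Methods: wavelet band energies, TBR and stage-binned ANOVAs for task EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet band energies, TBR and stage-binned ANOVAs for task EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eegdwt` analyses multichannel task EEG for markers of reasoning depth
and time-on-task fatigue: relative wavelet band energies and the
Theta/Beta ratio (TBR), compared across a resting state and two word
selection tasks — *picking* (free choice; shallow processing) and
*coordination* (matching an unseen partner's choice; deep processing) —
and across three *stages* of the experiment (trials 1–4, 5–8, 9–12).
This vignette documents the model, the estimators, the numerical
choices, and what the synthetic-data tests do and do not establish.

## Signal model and the synthetic cohort

The generator emulates the experiment the analysis was designed for:
10 participants, a 16-channel 10–20 montage sampled at 512 Hz, one
2-minute eyes-open rest block, then 12 picking and 12 coordination
trials whose string order is randomized per participant. Each channel
is modelled as

$$x(t) = \sum_{b} A_{b}(c, s)\,\sin(2\pi f_b t + \phi) + \varepsilon(t),$$

with one fixed representative tone per dyadic band
($f_\delta, f_\theta, f_\alpha, f_\beta$ = 2, 6, 10, 20 Hz), amplitudes
$A_b$ depending on condition $c$ and stage $s$ through the
`band_amplitude_map`, phases $\phi$ drawn independently per channel,
band and trial, and $\varepsilon$ a Gaussian background with a $1/f$
power spectrum (exponent 1 by default), realized independently per
trial segment. Fixed tones rather than band-limited noise keep the
spectral oracles sharp: a single oscillator's energy can be located
exactly by an FFT, so every stage of the pipeline can be checked
against an independent computation.

Two independence choices matter for the inferential checks. First, the
background is drawn independently per trial segment rather than as one
continuous process: a continuous $1/f$ background has slowly drifting
band energy, and because experiment stages are contiguous in time the
drift leaks systematic variance into stage contrasts — the pooled
interaction test then rejects a true null at roughly 8% instead of 5%.
Second, phases are independent across channels; any deterministic
cross-channel phase structure makes the (phase-dependent) dyadic
subband energies of different channels co-vary within an epoch.

Key defaults, chosen once as plausible for scalp EEG in signal units of
µV: background SD 1, tone amplitudes between 1 and 3. The default map
encodes the motivating effect pattern — picking flat across stages;
coordination starting with suppressed Alpha (1.5) and elevated Beta
(2.4) and ending with doubled Alpha (3.0), raised Theta and lowered
Beta, i.e. a +100% coordination-only late Alpha rise and a rising TBR;
rest with high Alpha and low Beta throughout. `amplitude_map_null()`
removes every condition and stage difference and is the basis of the
type-I calibration. No published amplitude or SNR figures exist for
this paradigm, so these values target detectability of the programmed
pattern, not fidelity to any particular dataset.

Randomization uses one master seed from which a fixed arithmetic
substream seed is derived per participant, so a single participant can
be regenerated bit-identically without generating the rest of the
cohort, and cohort generation is a pure function of the configuration.

What the generator deliberately omits: eye-blink and muscle artifacts,
volume conduction (channels are independent), participant-level random
effects, and non-stationarity within a trial. Passing tests therefore
show that the pipeline recovers programmed spectral structure from
realistic noise levels — not that it is robust to artifacts, nor that
pooled-ANOVA p-values would be calibrated on real data, where
observations within a participant are correlated (see the analysis
options below).

## Preprocessing

The stage order is fixed: band-pass filter → artifact hook → average
re-reference → down-sample → epoch → baseline-correct.

* **Band-pass 0.5–40 Hz**, as cascaded zero-phase 4th-order Butterworth
  high-pass and low-pass sections (`filtfilt`, so the effective
  magnitude is squared and the phase zero). A single 4-pole band-pass
  spanning 0.5–40 Hz is not flat in the middle of the band — it loses
  roughly 10% amplitude at 20 Hz — so separate sections are used; they
  are also better conditioned at the very low normalized high-pass
  cutoff (0.5 Hz at 512 Hz).
* **Artifact hook**: identity by default. Synthetic inputs are
  artifact-free; users with recorded data can inject ICA-based cleaning
  here without changing the stage order.
* **Down-sampling to 64 Hz** with a zero-phase 6th-order Butterworth
  anti-alias low-pass at 28 Hz (0.875 × the target Nyquist) before
  decimation. Filtering must precede decimation because 40 Hz content
  would otherwise alias below 32 Hz. The 6th-order/28 Hz choice keeps a
  20 Hz tone's energy loss under 5% while attenuating 40 Hz by more
  than 95%; content between ~26 and 32 Hz is inevitably shaved — no
  realizable filter is flat to the Nyquist edge.
* **Epochs**: half-open 1-s windows `[onset, onset + 64)` in 0-based
  samples, one per task event; the rest block is cut into consecutive
  non-overlapping 1-s epochs (120 for the default 2-minute block — the
  rest epoch count is a design choice here, as no standard exists).
  Windows running past the end of the record are dropped with a logged
  warning.
* **Baseline**: whole-epoch mean subtraction per channel. There is no
  pre-stimulus interval in this design, so a pre-stimulus baseline
  cannot be defined; subtracting the epoch mean removes residual DC
  without touching the bands of interest.

## Band energies, relative energies, TBR

Each 64-sample epoch trace is decomposed with a 3-level periodized
orthonormal DWT. Detail levels 1–3 cover Beta [16,32], Alpha [8,16] and
Theta [4,8] Hz; the level-3 approximation covers Delta [0,4] Hz. Band
energy is the sum of squared coefficients at the level; with periodic
boundary handling the transform is exactly orthonormal, so the four
energies sum to the epoch's total energy to machine precision
(Parseval), which the suite asserts at 1e-6 relative over random
epochs. Relative energy divides each band by the four-band sum; the
TBR is $E_\theta / E_\beta$ and is identical whether computed from
absolute or relative energies. Note the dyadic Alpha band [8,16] Hz is
wider than the canonical 8–12 Hz definition.

**Wavelet choice.** The decomposition wavelet is a parameter
(`haar`/`db1`, `db2`, `db4`, `db6`, `db8`) recorded in the output
metadata; the default is **db8**. Longer Daubechies filters have
sharper dyadic roll-off: with db4, a pure 10 Hz tone leaks ~18% of its
energy into the neighbouring bands (DWT Alpha fraction 0.82 against an
FFT band-power fraction of 1.0), while db8 keeps the worst-case
disagreement for in-band tones at ~0.07. Since the band statistics are
the scientific quantity, the default favours band selectivity; the
periodized transform stays orthonormal for every supported filter
length, so Parseval is unaffected.

Epochs with zero total energy (possible only for degenerate inputs such
as all-zero signals) are flagged, counted in the run log, and excluded
listwise from every analysis.

## Statistical analyses

Two analyses mirror the two questions:

1. **Condition × Band** (time-free): two-way ANOVA on relative energy
   with Condition (rest, picking, coordination) and Band (Theta, Alpha,
   Beta) as factors, one observation per epoch × channel × band. Delta
   is part of the relative-energy denominator but not a factor level.
   Tukey HSD post hoc contrasts are computed within each band at
   α = 0.05, with no additional correction across bands.
2. **Stage × Condition** (time-on-task): two-way ANOVA on relative
   Alpha or TBR with Stage (first/middle/last, from presentation order)
   and Condition (picking, coordination); rest epochs carry no trial
   index and are excluded. With the full design — 10 participants × 2
   conditions × 12 trials × 6 frontal electrodes = 1440 observations —
   the residual df is 1434 and the Stage term has 2 df.

Both are **pooled fixed-effects** ANOVAs treating every epoch × channel
observation as independent. That is the df-consistent reading of the
design (the residual dfs above follow from it directly), and it is
exactly calibrated for the synthetic generator, whose observations are
independent by construction. For recorded data, where epochs within a
participant are correlated, pooling anticonservatively inflates
significance; `aggregate_by_participant = TRUE` first averages to one
observation per participant × cell, giving a conservative
repeated-measures-style summary. Degenerate ANOVA inputs (zero total
variance) return a flagged result with `NA` statistics rather than an
error.

The frontal analysis set is {Fp1, Fp2, F3, F4, F7, F8} — the symmetric
prefrontal/frontal montage subset — configurable via `electrodes`
arguments throughout.

## Numerical and design choices

* Periodic DWT boundary handling keeps coefficient counts at exact
  powers of two and Parseval exact; the cost is wrap-around leakage for
  non-periodic content, negligible for 1-s epochs of oscillatory EEG.
* Stage binning is `ceiling(3 * index / n_trials)`, which for 12 trials
  gives 1–4/5–8/9–12 and generalizes to any multiple of 3.
* EDF output uses 16-bit quantization with a symmetric per-channel
  physical range; the write–read round-trip error is bounded by
  `phys_max / 32767` per channel. Events travel in a TSV sidecar.
* The pipeline's determinism contract: identical config + seed yields
  byte-identical feature tables, checked in the suite.

## Simulation-study problem sizes

The calibration and power studies in the test suite and acceptance
script run the full pipeline per cohort on a scaled configuration:
128 Hz acquisition, 1-s trials, a 2-s rest block. The full 16-channel
montage is retained even though only 6 channels are analyzed, because
average re-referencing subtracts the montage mean: with a montage
containing only the analyzed channels, the zero-sum constraint and the
oscillators' common-mode leakage couple exactly the rows entering the
ANOVA and inflate the pooled test (~9% type-I at the 6-channel
montage); with 16 channels the coupling is diluted to a negligible
level. The analysis table is still 10 participants × 2 conditions × 12
trials × 6 electrodes = 1440 rows, and hundreds of cohort replicates
stay cheap. Under the null map, the empirical type-I rate of the
Stage × Condition interaction over 500 cohorts is required to fall in
[0.03, 0.07] at α = 0.05; under the default (+100% late Alpha) map the
interaction must reject in at least 90 of 100 cohorts, and the stage
profile must show the programmed shape (coordination rising from below
flat picking to meet it).

## Known limitations

* The dyadic Alpha band [8,16] Hz mixes canonical alpha and low beta;
  results are not directly comparable to 8–12 Hz alpha power.
* Pooled ANOVA p-values are only valid when observations are
  exchangeable across epochs and channels — true for the generator,
  false for multi-channel recordings of one brain; use the aggregated
  variant for real data.
* TBR direction is reported, not interpreted: the literature contains
  both higher-TBR-higher-load and higher-TBR-lower-engagement readings,
  and the package takes no position.
* The EDF writer targets the plain 16-bit EDF profile written by this
  package (uniform sampling rate, no embedded annotations); it is not a
  general EDF+ implementation.
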