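# eegdwt

Wavelet band-energy analysis of task EEG, with a fully synthetic cohort
generator.

## The problem

When people solve tasks that demand different depths of reasoning — freely
*picking* a word from a list versus *coordinating* on the same word with an
unseen partner — their EEG band content shifts, and it also drifts with
time-on-task as engagement gives way to fatigue. `eegdwt` implements the
analysis pipeline for such an experiment end to end:

1. **Synthetic cohorts** — multichannel EEG (default: 10 participants,
   16-channel 10–20 montage at 512 Hz) with a 2-minute eyes-open rest
   block and 12 trials per task condition. Signals are 1/f Gaussian
   background plus band-limited oscillators (2/6/10/20 Hz) whose amplitudes
   are programmable per (condition, stage, band), so condition effects and
   time-on-task trajectories can be switched on or off exactly. Output is
   one EDF file + events TSV per participant.
2. **Preprocessing** — zero-phase band-pass (0.5–40 Hz), average
   re-reference, anti-aliased down-sampling to 64 Hz, 1-s epochs from each
   trial onset (the rest block is sliced into consecutive 1-s epochs),
   whole-epoch baseline correction.
3. **Band features** — a 3-level periodized discrete wavelet transform of
   each 64-sample epoch splits 0–32 Hz into the dyadic bands Delta [0,4],
   Theta [4,8], Alpha [8,16] and Beta [16,32] Hz. Per epoch and channel the
   package reports absolute band energies `E_b` (sums of squared
   coefficients; by Parseval these sum to the signal energy), relative
   energies `E_b / ΣE`, and the Theta/Beta ratio `TBR = E_θ / E_β`, over
   the frontal electrode set {Fp1, Fp2, F3, F4, F7, F8}.
4. **Statistics** — (a) a time-free Condition × Band two-way ANOVA on
   relative energies with Tukey HSD contrasts per band, and (b) time-on-task
   Stage × Condition ANOVAs on relative Alpha and on TBR, where *stage*
   bins trial presentation order into first (1–4), middle (5–8) and last
   (9–12).

## Worked example

```r
library(eegdwt)

cfg <- sim_config(n_participants = 10, fs_raw = 128, trial_duration = 1,
                  rest_duration = 2, inter_trial_gap = 0.25, seed = 7)
ft <- cohort_features(cfg)          # simulate + preprocess + features
anova_stage_condition(ft, "rel_alpha")
```

```
Two-way ANOVA on rel_alpha (N = 1440)
            term df       F       p
           stage  2 112.660 < 1e-16
       condition  1  18.219 2.1e-05
 stage:condition  2 105.748 < 1e-16
Residual df: 1434
```

The default amplitude map programs a coordination-only late-stage Alpha
rise (engagement → fatigue), so the Stage × Condition interaction is
strongly significant: 1440 observations = 10 participants × 2 task
conditions × 12 trials × 6 frontal electrodes, giving the design's
residual df of 1434. The matching stage profile
(`stage_profile(ft, "rel_alpha")`) shows picking flat across stages
(cell means 0.352, 0.345, 0.354) while coordination rises from 0.224 in
the first stage, below picking, to 0.443 in the last, above it — the
engagement-to-fatigue transition localized in the coordination task.

The same chain can be run file-based, with EDF output and TSV/PNG
analysis artifacts:

```r
run_all(cfg, "out/")    # or: Rscript inst/cli/eegdwt.R all --config cfg.yaml --outdir out
```

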