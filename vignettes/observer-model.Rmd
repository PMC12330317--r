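---
title: "The generative observer model and analysis choices in vpalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The generative observer model and analysis choices in vpalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpalign)
```

## The paradigm

A participant reaches to the remembered position of their unseen left index
fingertip. On *P* trials only proprioception indicates the target; on *V*
trials only a visual cue does; on *VP* trials both are present. In the
cue-conflict block the visual cue is displaced forward of the fingertip by
1.67 mm per VP trial, reaching 70 mm after 42 VP trials — too gradual to
notice. Endpoints on unimodal trials then reveal *recalibration*: the
proprioceptive estimate drifts toward vision and the visual estimate drifts
toward proprioception.

## The observer

`observer_params()` defines a generative observer with:

- sensory noise SDs `sigma_p`, `sigma_v` (mm, isotropic 2D),
- motor noise SD `sigma_m` on the indicating hand,
- a visual integration weight `w_v`, by default the minimum-variance value
  `sigma_p^2 / (sigma_p^2 + sigma_v^2)`,
- a recalibration rate `eta`, and
- baseline biases `b_p0`, `b_v0` (mm, 2D).

Endpoint laws (y shown; x is analogous with zero offset):

- P trial: `endpoint = p_target + b_p + eps_p + eps_m`
- V trial: `endpoint = v_cue - b_v + eps_v + eps_m`
- VP trial: `endpoint = w_v * (visual estimate) + (1 - w_v) *
  (proprioceptive estimate) + eps_m`

On each VP trial the observer perceives a conflict
`c = (v_cue - b_v + eps_v) - (p_target + b_p + eps_p)` and updates

```
b_p <- b_p + eta * w_v * c
b_v <- b_v + eta * (1 - w_v) * c
```

so the *lower-weighted* modality recalibrates more — proprioception moves
toward vision in proportion to the visual weight and vice versa. The update
law itself is a modelling choice (the underlying studies report the
phenomenon, not a mechanism); error-proportional exponential updating is the
simplest law consistent with gradual, conflict-driven drift. Two
consequences worth knowing:

- Under a fixed conflict the summed bias `b_p + b_v` approaches the imposed
  offset exponentially at rate `eta` per VP trial; total terminal
  recalibration never exceeds the 70 mm conflict for `eta <= 1`.
- Under veridical cues the observer perceives a standing conflict
  `-(b_p + b_v)`, so baseline biases are stationary only when they cancel;
  non-cancelling biases decay slowly over a 10-VP-trial baseline block.

A closed-form scalar recursion for the noiseless trajectory is implemented
independently in the test suite and used as an oracle for both the simulator
and the estimators.

## Cohort generator and default parameters

`simulate_cohort()` draws heterogeneous participants and runs full designs:
a two-session experiment (conflict vs veridical, with synthetic SAI measured
before and after each session), a three-group cTBS experiment
(veridical–conflict–veridical around stimulation of S1, M1, or sham), and a
visual-shift control (the same 70 mm ramp applied to V-only trials).

Defaults, chosen once at design time and frozen:

- `sigma_p ~ TN(8, 2)`, `sigma_v ~ TN(10.5, 2.5)` mm (floor 3 mm): places
  baseline 2D endpoint variances in the 50–92 mm² range typical of this
  paradigm and mean visual weights slightly below 0.5.
- `sigma_m = sigma_p`: encodes the analysis assumption that the indicating
  hand contributes half of the P-trial endpoint variance, which is what the
  0.5-correction in `corrected_variances()` presumes.
- `eta ~ TN(0.08, 0.015)` on [0.005, 0.5]: yields mean total expressed
  recalibration near two-thirds of the conflict, split roughly 1:2 between
  proprioception and vision at the default weights.
- Each participant's realized weight is drawn around the minimum-variance
  value with SD 0.25 (truncated to [0.05, 0.95]). This jitter, together with
  the `eta` spread, reproduces realistic between-subject dispersion of the
  two recalibration measures and their negative correlation; with weights
  pinned to the minimum-variance value the correlation would be far stronger
  than real cohorts show.
- S1 stimulation multiplies `sigma_p` by 1.3 and `eta` by 1.4 post-cTBS
  (M1 and sham: 1.0). Directions follow the finding that S1 disruption
  increases proprioceptive variance and recalibration; the magnitudes are
  declared defaults, not measurements.
- SAI coupling: `delta_sai = 105.94 + 1.80 * recal_p + 0 * recal_v + noise`
  (SD 15 %-units), applied in the conflict session only. The coupling is
  applied to the participant's *expressed*, endpoint-derived recalibration
  rather than the latent terminal bias, so the generative slope is
  recoverable by regression on measured behaviour without attenuation from
  endpoint measurement noise.

Seed policy: a master seed yields per-participant seeds via
`sample.int(.Machine$integer.max - 1)`, and each block gets its own derived
stream, so cohorts are bit-reproducible and participants are independent.

## Synthetic SAI traces

`simulate_sai()` renders each MEP as a damped sinusoid (onset 20 ms,
80 Hz, decay constant 60 s⁻¹) sampled at 5000 Hz for 100 ms, with
multiplicative amplitude jitter renormalized to mean one and optional
additive noise. Conditioned-trial amplitudes are scaled so that the
ratio-of-means SAI (20 conditioned / 20 unconditioned trials per timepoint)
equals the generative target exactly at zero noise; `sai_from_traces()`
recovers it through the same peak-to-peak (15–60 ms window) pipeline an
empirical analysis would use.

## Estimators

- `recalibration_p()`: mean of the last four minus the first four P-trial
  y-endpoints. `recalibration_v()`: 70 minus the same difference for V
  trials. Both reproduce the published definitions verbatim — including the
  approximation that the first four V trials already carry a small offset,
  which the acceptance bound accounts for in closed form.
- `block_wv()`: for each VP trial, the four nearest V and P trials by trial
  index (ties toward the earlier trial) give modality centroids; the weight
  is the relative distance of the VP endpoint from the proprioceptive
  centroid. Trials whose centroids are closer than half the pooled
  centroid-distance SD are excluded; a block mean requires at least three
  valid trials. Because distances are unsigned, the estimator shrinks toward
  0.5 as endpoint noise grows relative to the centroid separation — visible
  in recovery simulations away from `w_v = 0.5`.
- `endpoint_variance_2d()`: sample variance (n−1) of endpoint distances from
  their centroid; `corrected_variances()` subtracts half the P variance from
  both modalities, flagging (not clamping) negative corrected values.

## Inference

`fit_sai_recalibration_model()` fits a participant random-intercept model
(REML via `lme4`) of SAI change on four session-specific recalibration
predictors, with Wald confidence intervals, degrees of freedom
`n_obs - 5`, and hand-computed variance inflation factors
(`1 / (1 - R²_j)`). A singular random-effect fit falls back to OLS and is
reported as non-converged. `rm_anova_2x2()` uses the exact F = t²
difference-score identity for a fully within-participant 2×2 design, and is
tested against an independent sums-of-squares oracle. Group comparisons use
`stats::aov` with Tukey HSD or `kruskal.test`.

## Scope and limitations

The generator is a *behavioural emulator*, not a biophysical model. It is
meant to (a) give the estimators and inference code realistic,
ground-truth-known input, and (b) reproduce the qualitative sign structure
of the paradigm. It does not model reaction times, online corrections,
trial-order effects other than the offset ramp, EMG physiology beyond a
template MEP, or the attentional/awareness side of the task. Effect
magnitudes for stimulation groups are declared defaults; at the default S1
effect size, a three-group design with 27 participants per group detects the
proprioceptive-variance effect in roughly half of simulated replicates, so
single simulated cohorts should not be over-read. All problem sizes used in
tests and the acceptance script (cohort sizes, replicate counts) are package
choices made for runtime, not empirical claims.
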