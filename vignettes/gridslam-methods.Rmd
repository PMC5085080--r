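---
title: "Probabilistic grid-cell SLAM: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic grid-cell SLAM: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gridslam)
```

## The model

`gridslam` simulates spatial learning as simultaneous localization and
mapping (SLAM) carried out by two hippocampal-formation population codes:

* a **grid code** — eight modules of plane-wave phase accumulators with
  axis directions 60° apart and geometrically spaced wavelengths
  (`make_module_bank()`, default 30 cm × 1.42^(m−1)). A grid cell's rate is
  the rectified interference envelope `f = ∏ⱼ max(0, cos(pⱼ + ψⱼ))`;
  because every module integrates the same displacement, the joint phase
  state is an exact linear image of a nominal 2-D position, which the
  engine carries as the sufficient statistic;
* a **boundary code** — 228 boundary-vector cells (12 allocentric
  directions × 19 tuning distances: 8 short-range distances inside the
  13 cm somatosensory contact range, 11 long-range distances on a geometric
  ladder through the place-field-derived optima 16.2 and 33.8 cm). Cell
  (i, j) responds with a radial Gaussian around its tuning distance times a
  wrapped-Gaussian angular kernel (σθ = π/12), aggregated over hits by
  maximum.

A Rao-Blackwellized particle filter (`sifm()`) fuses three noisy cues:
self-motion (angular and linear displacement), egocentric boundary
observations raycast from the true pose, and — only when vision is
available — a compass observation. Each particle owns a grid phase state, a
private heading estimate and an **association map**: a lattice of map grid
codes (2 cm spacing) holding running-average weights onto the 228-cell
boundary code. Per step each particle

1. advances its heading (shared angular cue + private jitter) and position
   (shared linear cue along the private heading + one 2-D compensatory
   jitter, identical across modules within the particle and independent
   between particles);
2. rotates the egocentric boundary observation into allocentric
   coordinates through its private heading and activates the sensory
   boundary code;
3. updates its association map (visit-mass running average; a
   prediction-error delta rule with rate η is available as an alternative);
4. reads a predictive boundary code from the map at its position and
   computes the RMS prediction error over the regime-admissible cells
   (darkness: short-range cells only);
5. is reweighted by a Gaussian likelihood of that error
   (`exp(−err²/2σₑ²)`) times, under vision, a von Mises compass likelihood
   on its private heading.

Systematic resampling triggers when the effective sample size falls below
half the particle count (with a one-second refractory interval bounding
map-copy churn; `resample = "always"` reproduces per-step stochastic
resampling). Offspring copy phases, heading and map; compensatory noise
re-diversifies the cloud. During recall sessions learning is frozen, and
since maps then never diverge the engine shares a single map across
particles (bit-identical to per-particle copies).

Two ablations reproduce the model's negative controls: removing
compensatory noise (together with the equally per-particle private heading
jitter) makes all particles identical, so every correction channel —
boundary error and compass alike — becomes inert and the filter degenerates
to pure path integration; holding the prediction error constant
(`feedback_on = FALSE`) leaves the weights uniform forever while phases,
learning and resampling machinery run unchanged.

The compass enters through the importance weight rather than as a
per-particle state update. This is required by the degeneracy property
above: if any correction were applied deterministically inside each
particle, identical particles would still be corrected and the
compensatory-noise ablation would not reduce to pure path integration.

## Noise calibration

The sensory noise magnitudes are not printed in the source literature (they
live in cited prior analyses), so they are calibrated once, against the
model's own headline phenomena, and then frozen:

* `sigma_ang = 0.0125` rad/√s and `head_jitter_sd = 0.01` rad/√s. In a
  circular arena rotation is a pure gauge mode — no cue constrains it in
  darkness — so the net dark-session rotation equals the raw integrated
  angular noise. Stable dark-session maps over 10–20 minutes (bin-wise
  light↔dark correlations near 0.5) require net rotation below roughly one
  radian, bounding the sum of these two diffusivities. Because the
  rotation is a single random-walk realization per session, dark-session
  statistics at reduced replicate counts carry irreducible trial-to-trial
  variance (occasional sessions rotate far and correlate near zero).
* `cv_lin = 0.3`. The linear-displacement noise controls how fast *pure*
  path integration drifts. At smaller values the compensatory-noise
  ablation retains residual hexagonal periodicity (translational drift
  below two grid periods leaves autocorrelogram peaks intact); at 0.3 the
  ablation degrades the grid pattern while fused tracking is unaffected
  (decode RMSE under 10 cm in a 1 m arena). The ablation's residual
  gridness is itself realization-dominated: a single session's drift path
  decides how much periodicity survives, so small-sample means scatter
  widely around zero.
* `comp_noise_sd = 3` cm/√s. The compensatory jitter is the filter's
  proposal noise: it must dominate the per-step process noise (~0.6 cm)
  and it sets the posterior-cloud diffusion along locally unobservable
  directions. That diffusion is exactly what lets corridor-identity
  uncertainty reach the 15 cm corridor spacing in the hairpin maze —
  halving it suppresses fragmentation — while in darkness the resulting
  inter-contact blur trades off against map sharpness.
* `sigma_boundary = 1` cm, `sigma_compass = 0.1` rad, `compass_kappa = 5`,
  `sigma_e = 0.08` (keeps the median effective sample size in roughly
  0.3–0.9 of the particle count during nominal learning).

The 4× / 0.25× self-motion variance series is expressed as multipliers on
these defaults (`scale_selfmotion_noise()`).

## Synthetic trajectories

`generate_forage()` produces a correlated random walk with AR(1) speed
(mean 20 cm/s, SD 8, max 60) and weak AR(1) turning (turn-rate SD 1.5
rad/s, lag-1 heading-increment autocorrelation ≈ 0.03 — stronger turning
persistence reduces boundary-contact frequency enough to degrade
darkness persistence), steering away from walls
within 3 cm look-ahead. Twenty-minute sessions visit ≥ 95% of 2-cm
occupancy bins in arenas up to 1.5 m. The recorded heading at each sample
is the direction of the step that reached it, so noise-free cues
dead-reckon the path exactly. `generate_hairpin_path()` runs corridor
midlines with Gaussian lateral jitter (SD 2 cm, clipped to the corridor),
alternating easterly/westerly traversals; `generate_virtual_hairpin()`
replays the same geometry inside an open arena. What these generators do
*not* emulate: behavioural learning of the corridor task, speed-position
coupling, thigmotaxis in darkness, or head-scanning — so tests passing on
them certify the inference machinery, not rat behaviour.

## Analysis stack

Rate maps are occupancy-normalized 2-cm-bin histograms, masked below 0.1 s
occupancy and smoothed with a masked Gaussian (σ = 1 bin).
Autocorrelograms correlate overlapping valid bins per 2-D lag (minimum
overlap 20). Gridness is `min(r60, r120) − max(r30, r90, r150)` over an
annulus excluding the central field, in four variants (fixed annulus,
expanding-annuli maximum, and both after an elliptical correction fitted to
the six inner peaks); the expanding variant is the default reported
population statistic. The border score is `(cM − dm)/(cM + dm)` with fields
thresholded at 0.3 × peak and 200 cm² minimum area; in circular arenas the
perimeter counts as a single wall. The parametric rate-map correlation
classifier fits a single-boundary-vector-cell hypothesis (reconstructed
from arena geometry via raycasting) and an ideal interference-grid
hypothesis by multi-start Nelder-Mead maximization of the Pearson
correlation; a cell is unclassified when both correlations fall below 0.5.
Grid templates are least-squares lattice fits to the inner autocorrelogram
peaks (with sub-bin quadratic peak refinement); rescaling magnitude is the
axis-projected least-squares ratio of direction-matched peaks.

Attractor diagnostics read *per-particle* phase-matched cells (one cell per
grid code) rather than the weight-averaged ensemble: the paper-level
observation that activity collapses onto the unit diagonal during
successful recall is a statement about coherence *across grid codes*, which
the ensemble average hides by construction. The tracked module is the
smallest whose scale spans the arena extent, so coherence is measured on
the scale of the localization problem (no within-arena aliasing) rather
than of sub-field jitter.

## Numerical and scale choices

* dt = 0.1 s; 200 particles at full scale and 100 at reduced scale
  (the particle count is a design constant, not a reported quantity; all
  population statistics were checked to be insensitive between 100 and
  200).
* Association lattice: 2 cm spacing, kernel σ_g = 4 cm, support
  d_max = 12 cm; the resolution series halves/doubles all three.
* Reduced-scale protocols (the default) use 2 trials × 25 readout cells ×
  100 particles with 20-minute learning sessions, 10-minute recall
  sessions and 14 corridor traversals; full scale restores 10 × 200 × 200
  and 20 traversals. The acceptance script runs the same protocols at 80
  particles so a complete pass over every headline statistic stays within
  a quarter of an hour on one core; population statistics were checked to
  be insensitive across 80–200 particles.
* Map checkpoints are RDS files written at run time; configs and arena
  definitions are YAML; metric tables are CSV.
* Degenerate inputs: all-zero importance weights fall back to uniform with
  a logged degeneracy event; unvisited map regions predict a zero boundary
  code flagged `unvisited`; gridness and border score return NA when peaks
  or fields are undetectable.

## Known limitations

Rotation in rotationally symmetric arenas is anchored only by map
sampling lumpiness, so dark-session statistics inherit realization-level
variance from the rotational random walk; reduced-scale means over few
trials are correspondingly noisy, and the same applies to the residual
gridness of the pure-path-integration ablation. Hairpin fragmentation
depends on the corridor-identity uncertainty accumulated per traversal,
which sits near the corridor spacing at the calibrated noise level; the
fragmentation statistics (checkerboard structure, the sign of the
same-local/opposite-global correlation) are the most sensitive of the
reproduced phenomena and strengthen with particle count and traversal
number. The
connectionist (attractor-network) instantiation of the filter is out of
scope, as are olfactory and visual-landmark cues.
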