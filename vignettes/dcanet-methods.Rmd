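---
title: "Multi-modal attention networks for longitudinal motor-UPDRS prediction"
author: "dcanet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal attention networks for longitudinal motor-UPDRS prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

At-home telemonitoring of Parkinson's disease produces long, irregular
per-patient series of voice recordings: each visit yields 16 acoustic
dysphonia measures (jitter and shimmer families, NHR/HNR, RPDE, DFA, PPE)
paired with a motor-UPDRS score. The task is longitudinal regression:
given a window of a patient's past visits, predict the motor-UPDRS score
at the next assessed visit. `dcanet` implements a complete pipeline for
this task — feature engineering, a dynamic context-aware fusion network,
its training protocol, and a repeated patient-level cross-validation and
ablation framework — together with a synthetic cohort generator so that
every stage can be exercised and tested without external data.

## The model

Four per-timestep feature blocks (modalities) feed the network:

* **voice** (146 columns): each acoustic measure expanded into raw,
  Savitzky–Golay-denoised (window 5, quadratic), velocity and
  acceleration against actual day gaps, trailing rolling mean/sd
  (3 visits), within-patient z-score (stability constant 0.01, clipped at
  ±5), trailing rolling skewness/kurtosis (5 visits), plus a voice
  instability index and the HNR/NHR quality ratio;
* **clinical** (9 columns): visit timing markers and *lagged* UPDRS
  dynamics only (lag-1/lag-2 scores, their delta, a 3-visit delta trend,
  lagged disease stage, a ±0.5-point progression-rate code), so no
  clinical feature touches the target visit's score;
* **meta** (3 columns): age, sex, test time;
* **text** (768): an embedded clinical-narrative summary of the patient's
  longitudinal statistics, tiled across timesteps.

Each modality has its own encoder (stacked bidirectional LSTMs plus
multi-head self-attention for voice; position-wise GELU dense stacks for
the rest), all emitting `T × h_d` sequences. The fusion layer applies
per-modality self-attention, mean-pools each attended sequence over valid
timesteps, concatenates the pooled vectors and passes them through a
learned softmax layer to obtain convex modality weights
`α = softmax(W_c h_context + b_c)`; the fused sequence is
`H_f[t] = Σ_m α_m A_m[t]`. Because the weights are convex, the fused
sequence lies pointwise in the convex hull of the attended modality
streams — an invariant the test suite checks. A temporal block (two
bidirectional LSTM layers with residual connections, then self-attention
under a strict causal mask) and a three-layer GELU head produce one
scalar prediction per window from the final timestep.

Two readings of the fusion equations were possible: the pooled vectors
could either *be* the fused output (which collapses the time axis) or
*drive the weights only*. We implement the second — pooling informs `α`,
and the weights recombine the full attended sequences — because the
downstream temporal block requires a `T × h_d` sequence and the
architecture explicitly models time after fusion.

Sequence windows cover the `T = 10` visits up to and including the target
visit; shorter histories are left-padded with zeros and masked. Padded
timesteps are zeroed at the input, excluded from attention (as keys and
queries) and from pooling, so predictions are exactly invariant to
whatever values sit in padded positions. Voice and meta features at the
target timestep are contemporaneous measurements and are legitimate
inputs; the model never sees the target visit's UPDRS (or any later
score) in any feature cell, which a perturbation test verifies globally.

## Clinical narratives and their embedding

For each patient a fixed clinical-summary template is instantiated with
longitudinal statistics (mean/sd and per-visit slope of motor UPDRS,
severity/pattern/variability labels, jitter/shimmer/HNR means and trends,
monitoring-pattern numbers). Label thresholds are configurable choices:
severity reuses the stage grid (mild ≤ 20 < moderate ≤ 40 < severe),
the progression pattern uses a ±0.05 points/visit dead band, "high"
variability means SD > 5 points, voice trends use a dead band of 5% of
the patient mean per visit, and the impairment label uses common
clinical-voice norm ranges (significant if jitter ≥ 1% or shimmer ≥ 0.06;
mild if jitter < 0.4% and shimmer < 0.02).

The default narrative mode (`full_history`) computes these statistics
over the patient's complete series, which deliberately reuses later
same-patient visits in the text channel; this is safe under patient-level
cross-validation (no other patient's data is involved) but is not
causally clean, so a `causal` mode that truncates the history at each
target visit is provided and its invariance to later visits is tested.

The packaged embedding backend is a deterministic feature-hashing
projector designed to emulate the *geometry* of a pretrained sentence
encoder offline: word tokens hash to signed coordinates, while numeric
tokens are keyed by their preceding word and written as multi-scale
sine/cosine features of their value. The Fourier construction matters:
discretely hashing "28.3" would make every unseen value an unrelated
direction, so summaries of held-out patients would embed as noise,
whereas a sentence encoder maps similar summaries to nearby vectors. Any
encoder exposing `dim` and `encode()` can be plugged in instead — e.g. a
pretrained transformer sentence encoder via **reticulate** — and nothing
in the pipeline assumes more than the 768-dimension contract.

## Training protocol

The loss is mean Huber with δ = 2 UPDRS points (robust to occasional
extreme score fluctuations, differentiable everywhere), plus an L2 kernel
penalty (λ = 3e-4 reference, 5e-4 ablation preset). Optimisation uses
AdamW (initial learning rate 3e-4, decoupled weight decay 0.005), global
gradient-norm clipping at 1.0, batch size 16, a piecewise learning-rate
schedule (constant for 10 epochs; 5% decays at epochs 10/20/30; a 10%
decay at epoch 60; 15% decays every 30 epochs thereafter), plateau
reduction (factor 0.5, patience 10, floor 1e-6), and early stopping with
best-weight restoration. The validation holdout is 15% of training
*patients* — whole patients, consistent with the patient-level leakage
stance — rather than a window-level split.

Feature scaling is median/IQR robust scaling with post-scaling clipping to
[−5, 5] for voice, meta and numeric clinical columns (categorical stage
and progression codes pass through); text embeddings are mean-centred.
Scalers are fitted on training-fold patients only — fold bookkeeping
asserts this.

Two numerical choices deserve explanation:

* **Internal target standardisation.** `train_model()` standardises the
  target with training-fold statistics and rescales the Huber elbow by the
  same factor, so the robustness transition still happens at exactly 2
  UPDRS points; predictions are mapped back to raw units. Under Adam with
  learning rate 3e-4 every parameter moves at most ~3e-4 per step, so an
  output layer that must span tens of raw UPDRS points from
  layer-normalised O(1) activations needs tens of thousands of steps to
  get there; at unit target scale the same geometry is reachable within
  the ablation preset's 50-epoch budget. The transformation is exactly
  affine and is inverted before any metric is computed.
* **Output-bias initialisation** at the (standardised) training-target
  mean, i.e. the climatological predictor, a common initialisation for
  regression heads.

The network itself is implemented in R with RcppArmadillo kernels for the
LSTM recurrences and multi-head attention (forward *and* backward passes);
every backward path is validated against central finite differences in
the test suite, which is the strongest correctness check available for
hand-derived gradients.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws a 42-patient cohort that mirrors the published
telemonitoring cohort's headline statistics: ages ~ normal(64.4, 9.2)
truncated to [40, 90]; two-thirds male; 120–150 visits per patient over
180 days (≈ 5.9 months); baseline motor UPDRS uniform on [8, 35] with a
normal(0.02, 0.015) points/day slope, which keeps the cohort in the
early-to-moderate regime (essentially no one above 40 points); and AR(1)
visit-level noise (ρ = 0.7, marginal sd 1 point) so that lag and rolling
features carry real temporal signal rather than white noise. Acoustic
measures couple linearly to the latent severity with multiplicative
log-normal noise — multiplicative rather than additive so strictly
positive measures stay positive — with positive loadings for the
jitter/shimmer/NHR families and a negative loading for HNR, calibrated so
intercepts sit at the published cohort means and the induced spread is of
the order of the published SDs.

What passing tests on this cohort do **not** show about real data: the
generator's severity trajectories are linear with stationary noise, its
acoustic coupling is monotone and patient-homogeneous, there is no
missingness, no medication state, no recording-equipment artefacts, and
the narrative channel summarises exactly the statistics the template
names. Results on the synthetic cohort validate the machinery (shapes,
leakage freedom, optimisation, bookkeeping, directional modality
effects), not clinical performance.

## Evaluation framework

`repeated_patient_kfold()` assigns whole patients to k folds per
repetition (fresh seeded shuffle per repetition, seed + r), so every
patient is tested exactly `repeats` times; `run_cv()` refits scalers and
a freshly initialised network per fold and pools test-window predictions.
Aggregation reports mean, sample sd, min/max/range, a t-based 95% CI
(the CI method is unstated upstream; t over folds is the conventional
choice) and CV%. `paired_t_test()`, `kendalls_w()` (tie-corrected) and
`bland_altman()` supply the statistical comparisons; `ablation_runner()`
re-runs the six standard modality configurations under identical fold
assignments and per-fold seeds with the ablation preset (hidden 128,
dropout 0.2, L2 5e-4, 4 heads, ≤ 50 epochs, patience 10);
`baseline_harness()` fits ridge (glmnet), gradient-boosted trees
(xgboost), a random forest (ranger) and a single-layer recurrent
regressor on flattened final-timestep features under the same folds.
Baselines do not receive the text embeddings by default (a flag adds
them).

## Problem sizes

Experiments in the test suite and the acceptance script run at desk
scale, chosen once as the package's standard configuration: the default
42-patient cohort, the ablation preset, one repetition of patient-level
5-fold CV, and training on an evenly spaced subsample of 20 windows per patient
(validation monitoring uses up to 32 windows per held-out patient so the
early-stopping signal stays smooth). Consecutive windows share T−1 of T timesteps, so a spaced
subsample retains nearly all training information while bounding the
optimisation budget; evaluation always uses *every* window of the
held-out patients. Unit tests use still smaller cohorts (4–8 patients,
8–16 visits) and narrow networks (hidden 8–16), which exercise identical
code paths.

## Degenerate inputs and tie-breaks

Series shorter than the denoiser window are returned unchanged; rolling
moments on windows too short for a moment to exist are defined as 0
(`min_periods = 1`); the within-patient z-score guards zero variance with
its ε; the min–max normalisation in the instability index maps constant
traces to 0; fully masked attention rows output zeros rather than NaN so
padded short histories cannot poison gradients; a degenerate IQR falls
back to scale 1; zero-variance paired differences are flagged as exact
ties (t = 0, p = 1 when the mean difference is also zero); zero-variance
targets leave R² undefined and flagged rather than silently 0 or 1.

## Known limitations

* The packaged text encoder is a hashing projector, not a pretrained
  language model; it preserves embedding geometry, not semantics. Plug in
  a real sentence encoder for production use.
* `full_history` narratives reuse later same-patient data by design
  (mitigated by patient-level CV); use `causal` mode when a strictly
  causal pipeline is required.
* The centred Savitzky–Golay denoiser uses within-window future visits;
  this is confined to the input window and a `causal_denoise` variant is
  available.
* Training runs on a single CPU; the implementation favours correctness
  and reproducibility (seeded, deterministic given the seed) over
  throughput, and published-scale experiments (8 repetitions, 240
  ablation trainings) are API-supported but meant for larger compute.
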