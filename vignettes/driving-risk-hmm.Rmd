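---
title: "Modelling driving risk during lane changes with a two-state HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling driving risk during lane changes with a two-state HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

An overtaking manoeuvre decomposes into four stages — car following,
perception, intention, execution — during which the driver's workload, and
with it the risk of an unsafe action, rises and falls. Workload leaves
traces in physiology and vehicle handling: fixation durations lengthen
when visual information is hard to extract, saccade amplitudes grow with
scanning effort, the SDNN of the R–R intervals contracts under strain and
fatigue, and speed management changes with traffic state. None of these
signals observes risk directly; `riskhmm` therefore treats the risk state
as hidden and the indicators as its emissions.

The model is a two-state hidden Markov model. The hidden chain
`q_t ∈ {safe, dangerous}` evolves with transition matrix `A` and initial
distribution `Π`; each step emits a 4-vector (fixation duration, saccade
range, SDNN, average speed, z-scored with training-set statistics) from a
state-specific Gaussian mixture with diagonal covariances,
`b_j(o) = Σ_m C_jm N(o; μ_jm, U_jm)`. Estimation is Baum–Welch EM:
log-space forward and backward lattices give state and mixture posteriors,
which re-estimate `Π`, `A`, `C`, `μ`, `U`; iteration stops when the
relative log-likelihood gain drops below `tol`. Decoding uses the Viterbi
dynamic programme with ties broken toward the lower state index;
forecasting propagates the forward-filtered posterior through `A^h`.

**Temporal unit.** The chain steps once per lane-change *event*, and
training sequences are the consecutive events of one driver's session.
This is the only reading consistent with a reference transition matrix
whose off-diagonal mass is large (≈0.25 both ways): a chain stepping
within the four stages of a single event, whose state is essentially
constant, would have to be nearly diagonal. The four stage rows of an
event are averaged into its observation vector; the per-stage table
re-decodes the same test events with one stage's rows substituted as the
observations, mirroring how stage-specific results are produced from a
single trained model in field studies.

**Topology.** A left-to-right chain is the textbook choice for
progressive processes, and the package supports it
(`structure = "left_right"`: only self- and forward transitions, absorbing
final state, a zero pattern that EM preserves exactly). The default,
however, is ergodic: recovery from a dangerous episode back to safe
driving is empirically frequent — the reference field estimate puts the
dangerous→safe probability at 0.2537 — and a two-state left-to-right chain
forbids it.

**State labelling.** After fitting, the state with the higher SDNN
emission mean is labelled *safe*: larger time-domain HRV indicates an
adaptable cardiac autonomic state, while strain contracts it. An exact tie
keeps state 1 as safe and warns. The per-feature contribution matrix
(`state_contributions()`) summarises separation as the absolute
safe–dangerous mean gap weighted by each state's precision, row-normalised
— a 2×4 row-stochastic summary comparable in shape to the per-feature
emission shares printed for field-trained models.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `K` | 1 | components | one Gaussian per state is identifiable from ~400 training events; mixtures are available when emissions are visibly multimodal |
| `tol` | 1e-6 | relative log-lik | EM stops within a few iterations of practical convergence |
| `max_iter` | 500 | iterations | safety cap; well-separated data converges in under 20 |
| covariance floor | 1e-6 × training variance | — | prevents component collapse on (near-)degenerate features |
| `split` | 0.85 | fraction | 425-train / 75-test on 500 events, the canonical protocol size |
| LF band | 0.04–0.15 | Hz | HRV convention (sympathetic dominance) |
| HF band | 0.15–0.40 | Hz | HRV convention (parasympathetic/respiratory) |
| R–R resampling | 4 | Hz | cubic-spline tachogram interpolation before Welch |
| Welch segment | min(256, n), 50% overlap, Hann | samples | 64 s segments at 4 Hz resolve 0.016 Hz |
| refractory | 250 | ms | physiologic upper bound near 240 bpm |
| peak threshold | 0.6 × rolling 2-s max | — | adaptive to amplitude drift |
| screening tiers | 0.05 / 0.01 / 0.001 | probability | strict inequalities; a value *equal* to a threshold does not pass |

Initialisation follows the averaging method for the chain
(`Π = (0.5, 0.5)`, `A` uniform within the topology) and a seeded 2-means
split of the pooled observations for the emission means; every source of
randomness takes an explicit integer seed, and all fits record their
log-likelihood trace.

## What the synthetic generator emulates — and what it does not

`sim_config()` encodes the study conditions as defaults rather than as
tuning knobs: 500 events over 25 drivers; event-level risk dynamics with
the reference transition matrix (safe persistence 0.7529, dangerous
persistence 0.7463) and initial safe share 0.8584; emission means
separated by roughly three pooled SDs on each indicator (safe 250 ms /
4° / 60 ms / 55 km/h against dangerous 400 ms / 8° / 35 ms / 65 km/h, SDs
40 / 1.2 / 7 / 3); a 5% chance that a driver's self-assessment disagrees
with the hidden state. LOS I–IV and four driving-duration bins add
additive mean shifts following the qualitative field trends (fixation and
saccade grow with congestion until saturation then contract; SDNN declines
with congestion and accumulated driving time; speed falls with
congestion). A stage "activity profile" (defaults 0.7 / 0.9 / 1.2 / 1.1)
scales the dangerous-minus-safe displacement per stage, so intention and
execution look most distinct — the ordering field studies report.

The raw streams are deliberately minimal stochastic processes with the
right measurable structure: R–R intervals are Gaussian draws
*moment-matched* so the realised sample SD equals the event's SDNN target
exactly (then clipped to the physiologic 300–2000 ms); gaze is an
alternating fixation/saccade renewal process; speed is a mean-reverting
Gaussian walk (AR coefficient 0.9, innovations at 0.3 of the state SD).
Stage durations are fixed proportions (40/20/20/20) of a 60 s event, as no
standard segmentation exists; stage boundaries are emitted as ground truth
and no boundary detection is attempted. Driving-duration bins advance with
an event's position in its driver's session; LOS is drawn uniformly.

Consequently, passing tests demonstrate algorithmic correctness — exact
recursions, EM monotonicity, parameter recovery, determinism — under
idealised Gaussian, renewal and AR(1) emissions. They do not demonstrate
robustness to what real recordings add: ectopic beats and electrode
artefacts, gaze-tracking dropouts, non-Gaussian and heteroskedastic
features, drivers with idiosyncratic baselines, or mis-segmented stages.
The synthetic accuracy ceiling is set by the 5% label noise, so held-out
accuracies in the mid-90s say nothing about field accuracy beyond
consistency of the machinery.

On synthetic features the two-factor screen typically admits the eye and
HRV indicators but can miss the small configured duration effect on speed:
within-group variance there is dominated by the safe/dangerous mixture.
The pipeline therefore reports the screening outcome but trains on the
configured observed-input set (the four indicators above), mirroring how
the input set is fixed in the protocol it emulates rather than re-derived
per run.

## Screening and selection choices

`I1` is exposed in both senses in circulation: the pairwise ratio of two
groups' sample variances, and the one-way ANOVA between/within mean-square
ratio (the F statistic); the published indicator tables do not disambiguate
which produced them, so both are available and the ANOVA form is the
default in `screen_features()`. Selection gates on `I2 < 0.05` for *both*
factors (LOS and duration) in the intention and execution stages — the
stages whose indicators carry the risk signal; the kept eye-movement
indicators are only significant there. No `I1` threshold is gated on: when
needed, the critical F value at α = 0.05 for the groups' degrees of
freedom is the natural reference. No multiple-testing correction is
applied across the 4-stage × 2-factor × 8-feature grid, matching the
protocol emulated. One representative per signal category is kept — SDNN
for the time-domain HRV pair {SDNN, CV} — as an explicit configuration
rather than a hidden rule: CV passes every gate but duplicates SDNN's
information (CV = SDNN / mean R–R). Non-representative members of an
active category are never auto-promoted, which keeps selection monotone as
I2 values shrink. Disabling the constraint
(`screening_config(category_representative = NULL)`) admits CV.

Published tail probabilities censored in print as "< 0.001" are stored
with a censoring flag and the numeric stand-in 0.0005; under strict
thresholds down to 0.001 any value below 0.001 behaves identically. One
printed value, pupil-diameter variability at exactly 0.050 in the
intention stage, is a deliberate strict-inequality test case: it must not
pass.

## Numerical choices and degenerate inputs

* All lattice computation is in log space; `-Inf` blocks (structural
  zeros, impossible emissions) propagate correctly through a two-argument
  log-sum-exp. A sequence with zero total likelihood raises an error
  naming the problem rather than returning NaNs.
* Forward- and backward-derived log-likelihoods are both computed and
  asserted to agree (1e-8) as an internal consistency check.
* SDNN uses the n−1 sample denominator; fewer than two intervals is an
  error, never a silent zero. Stage windows with no fixations yield NA
  ("missing") features and the row is flagged incomplete and excluded from
  training; nothing is imputed.
* LF/HF requires a ≥120 s record; at the ~12–24 s stage scale it is
  reported NA, which is why it is an extended rather than selected
  feature.
* A collapsed mixture component (vanishing responsibility) is re-spawned
  once at a random data row; a second collapse is an error. A state losing
  all occupancy is an error.
* `stationary_distribution()` refuses (near-)identity or reducible chains,
  where the distribution is not unique.
* Model JSON is written with 17 significant digits, so save→load
  round-trips parameters and likelihoods bit-exactly, and files carry a
  `schema_version` that is checked on read.
* The training split is seeded and stratified by perception label with
  largest-remainder rounding, so a 0.85 split of 500 events always holds
  out exactly 75. Training events form gappy per-driver chains; contiguous
  runs become training sequences, and held-out events are decoded as
  per-driver subsequences.

## Problem sizes used by the test-suite experiments

The exhaustive-enumeration oracles run at T ≤ 10 with two states (≤ 1024
paths), where brute force is exact and instant. Parameter recovery uses
1000 sequences of length 20 from a 3-SD-separated generator — enough that
the transition matrix is recoverable within ±0.05 elementwise and emission
means within ±0.1 SD. The end-to-end experiment uses 500 events (the
canonical protocol size), and chain-convergence checks use 10^5 steps,
where empirical transition frequencies sit within ±0.01 of the truth.
These sizes were chosen as the smallest at which the corresponding
statistical claims are comfortably testable.

## Known limitations

* The packaged reference parameter set carries a printed 2×4 per-feature
  emission-share matrix that is not a Gaussian-mixture parameterisation;
  its estimator is not recoverable, so it is consumed as a summary
  (`printed_contribution_matrix`) and never claimed reproducible. The same
  source also quotes state-maintenance probabilities of 90.67%/86.42% in
  its conclusions, inconsistent with its own printed transition matrix
  (75.29%/74.63%); the fixture carries the matrix, which satisfies the
  normalization invariants.
* One published per-stage probability row (perception: 87.40 safe, 22.60
  dangerous) does not sum to 100 and is presumed a typo; the package
  enforces normalization and does not attempt to match that row.
* Only two hidden states, diagonal-by-default covariances, and offline
  (batch) EM are provided; streaming estimation, semi-supervised use of
  partial labels, and TTC-style kinematic baselines are out of scope.
* The R-peak detector is a plain adaptive-threshold local-maximum picker
  with a smoothing pre-filter — adequate for clean chest-lead signals and
  the packaged synthetic waveforms, not for heavily artefacted ambulatory
  recordings.
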