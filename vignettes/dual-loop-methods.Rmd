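---
title: "Models and methods behind topogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind topogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`topogate` implements a complete dual-loop neuro-adaptive pipeline against
its own synthetic data generator. This vignette explains the models, the
tunable parameters and their defaults, the numerical choices, and what the
passing tests do — and do not — establish about real data.

## 1. The session generator and what it emulates

A session is a warm-up phase (default 300 s, baseline task only) followed by
a task phase (default 600 s) in which three event types arrive as
independent homogeneous Poisson processes: secondary-task blocks
(1.0/min, 20 s each), perturbations (2.0/min), and time-critical hazards
(2.0/min). Event-anchored classes follow the operational convention:
windows starting within 2.5 s after a perturbation are surprise/startle
(SU); windows overlapping a secondary-task block are diverted attention
(DA); all others channelized attention (CA); precedence SU > DA > CA. The
2.5 s figure is the midpoint of the conventional 2–3 s post-perturbation
interval and is shared by the labeling rule and the peak-load mask. The
default rates put the pooled class mix at ≈ 68/24/8%, the center of the
reference ranges for this kind of event-anchored protocol (CA 60–70,
SU 5–10).

The latent workload drive ℓ(t) ∈ [0, 1] is a smoothed state (time constant
3 s): baseline 0.30, +0.35 plateau inside secondary-task blocks, a 0.50
spike decaying with τ = 2 s after perturbations, −0.15 × haptic level while
assistance is active, plus a slow deterministic baseline drift (SD 0.15,
periods 97 s and 31 s, phases drawn from the session seed). The drift
exists because a perfectly flat warm-up latent would make the warm-up
calibration SD meaningless — the thresholds τ = μ + 1.5σ and
κ_red = μ + 2σ would be quantiles of estimation noise rather than of
workload variability — and because real operators show spontaneous
workload fluctuation within a behavioral state.

EEG is synthesized per channel as 1/f background (SD 10 in
microvolt-like units) plus band-limited θ/α/β oscillations whose
amplitudes follow fixed topographies (frontal θ, posterior α) and
load/state gains: θ and β rise with load, α falls, and F4/F3 α amplitudes
split as exp(±FAA-gain·ℓ/4) so the measured frontal alpha asymmetry grows
linearly with load. Each class adds a spatialized signature (DA: frontal θ
up, α down; SU: broadband β and θ up) scaled by `class_contrast`
(default 1; the "strongly separable" profile used by the decoder-level
checks sets 3). A 50 Hz line component and sparse 10×-SD artifact bumps
(100–300 ms, 2/min) give the notch filter and ASR something to remove.
Signature magnitudes were fixed once so that (i) the equally-weighted
z-score of the *ground-truth* band powers correlates with ℓ(t) at
r ≈ 0.97 (the recoverability ceiling), and (ii) workload-state shifts are
a realistic number of warm-up SDs — the first draft separated states so
sharply that the clipped CLI saturated far beyond plausible overload
exposure levels. An optional global band-power modulation
(`amp_mod_sd`, default 0) adds further spontaneous variability; it is off
by default because at realistic scales it masks the load signal in the
channel-averaged features — a known limitation of the generator's additive
design.

What the generator does *not* emulate: volume conduction from cortical
sources, eye/muscle artifact morphology, electrode impedance drift,
inter-individual spectral idiosyncrasy, or learning/fatigue across a
session. Passing tests therefore demonstrate internal consistency of the
pipeline — that each stage recovers what the generator put in — not
field-level decoding performance.

## 2. Preprocessing

Filtering is applied to the continuous record before windowing (avoiding
per-window edge transients): a windowed-sinc FIR band-pass 1–40 Hz (tap
count from a 0.8 Hz transition at the 1 Hz edge; ≥ 20 dB at 0.2 Hz) and a
49–51 Hz FIR notch (≥ 30 dB at 50 Hz, < 1% ripple at 10 Hz), both applied
with exact linear-phase compensation via FFT convolution with reflection
padding. Windows are 1 s with 100 ms stride; per-window normalization is a
per-channel z-score (idempotent; constant channels map to zero), so
downstream band powers are relative to within-window variance — the
per-participant z-scoring of the CLI compensates the absolute-scale loss.

Artifact subspace reconstruction is calibrated on the warm-up: the
reference covariance C₀ defines a whitening transform under which clean
data are isotropic. For each 0.5 s block, principal components of the
whitened block whose RMS exceeds the clean expectation by more than
`cutoff` warm-up SDs are removed by an orthogonal projection in raw sensor
space along the implicated directions (so the operation is an exact
contraction: output energy never exceeds input energy). The default cutoff
is 10: measured whitened block-variance ratios are ≤ 1.3 for clean
stationary data, 6–9 for legitimate workload-driven band-power shifts, and
≈ 50 for a 10×-SD artifact, so a 5-SD threshold — sometimes quoted as an
aggressive real-time setting — would remove the very signal this pipeline
measures, while 10 SDs separates artifacts from workload cleanly.

## 3. Maps and the workload index

Band powers use Welch's method exactly as parameterized for online use:
Hann taper, 128-sample segments (0.5 s), 50% overlap, 2 Hz resolution.
Bins are assigned to bands by center frequency, lower-inclusive: θ bins
{4, 6}, α bins {8, 10, 12} (the α upper edge is carried at 13 Hz so the
12 Hz bin belongs to α and β opens at 13), β bins {14…30}.

Electrode positions (the standard 14-label wireless montage at 10–20
coordinates) are projected by the azimuthal equidistant map (planar radius
= arc length from the vertex) and interpolated with an exact thin-plate
(biharmonic) spline — kernel r²log r plus an affine part — onto a 32×32
grid; pixels outside the scalp disc (1.1 × the outermost electrode radius)
are zero. The interpolant reproduces electrode values and affine fields to
machine precision, which the acceptance suite asserts at 1e-6.
Interpolation acts on log₁₀ band power (stabilizes the dynamic range);
FAA enters as a constant fourth plane. Sequences are K = 10 consecutive
stacks (span 1.9 s), emitted only once K stacks exist.

The formula CLI combines z-scored channel-mean band powers and FAA with
equal weights λ = (1, 1, 1, 1) by default (the weights are calibration
parameters without stated values; equal weighting is the neutral choice
and is exposed in the profile). Robust normalization is a clipped min–max
over the warm-up 5th/95th percentiles. Because the warm-up never contains
high-load epochs, task-phase CLI saturates at 1 under strong load — a
structural property of warm-up-bounded normalization that also bounds how
well the clipped index can correlate with the latent load (the pipeline
achieves r ≈ 0.73–0.78 on default sessions against a 0.97 ground-truth
ceiling). The thresholds live on the normalized scale; for a roughly
normal warm-up, κ_red = μ + 2σ lands near or above 1, so the CLI branch of
the safety override rarely fires and the SU branch carries the safety
load — a faithful consequence of the published threshold definitions.

## 4. Decoder

The decoder is hand-authored (no deep-learning framework is required):
compiled im2col/col2im and pooling kernels, BLAS matrix products, explicit
backpropagation (verified against numerical differentiation at 1e-4
relative tolerance in the suite), and Adam. Convolutions use same-padding,
so the spatial trace is 32→16→8 and the flattened per-step feature is
8·8·64 = 4096; with the LSTM (64 units) and both heads the default
parameter count is exactly 1,089,204, asserted in tests. The CNN is
applied per time step with shared weights. The joint loss is
cross-entropy + 1 × MSE on the CLI head; in synthetic training the CLI
target is the ground-truth latent load. Class imbalance is left to plain
cross-entropy (no re-weighting), and sequences are labeled by their final
window (the sequence is trailing context for the current state). Splits
are chronological 70/10/20 with floor boundaries; no shuffling across
boundaries.

Defaults follow the published training recipe (Adam 1e-4, weight decay
1e-5, dropout 0.25/0.3). The desk-scale profile used by the tests and the
acceptance script raises the learning rate to 1e-3 with early stopping
(patience on validation loss): at a few hundred sequences and tens of
updates, the 1e-4 schedule cannot leave its initialization — it is sized
for cohort-scale data. Problem sizes in the checks: two sessions of 90 s
task + 45 s warm-up at `class_contrast = 3`, sequences subsampled at
stride 8 (≈ 220 sequences), 6–8 epochs. Under these conditions the map
variant reaches ≥ 0.90 validation accuracy and the representation
ordering maps ≥ spectral ≥ raw − 0.02 holds in the median over five
training seeds. The comparison variants keep the recurrent trunk and the
training budget: RAW uses a 1-D convolutional encoder over the normalized
channel×time windows, SPECTRAL a dense encoder over the 43-vector
(14 channels × 3 bands log power + FAA).

## 5. Controller

The controller is one shared two-layer tanh network with two categorical
heads (pilot, engineer) plus a separate centralized critic — the simpler
of the two readings of joint-action training with decentralized execution.
Training samples actions; evaluation takes each head's modal action. The
environment serves decoder-free observations during training (the noisy
latent as CLI estimate, ground-truth class with 5% label noise): rolling
out EEG synthesis and decoding inside the RL loop would multiply its cost
without changing what the policy can learn, and the spec-level switch
between decoder-head CLI and formula CLI is preserved at evaluation time.

Rewards follow the safety-first weighting (w = 10/1/0.5/0.1/0.1 with
α = 1, β = 5, η = 0.1); reaction times enter in seconds with a 0.5 s
target, i.e. RT* = 500 ms, near the open-loop mean. The episodic
constraints (mean overload ≤ 0.15; summed RED-state attempts ≤ 0.05) are
implemented as per-step Lagrangian shaping — exact for the sum-type
communication cost, exact in expectation for the mean-type load cost — with
projected dual ascent λ ← max(0, λ + η_λ(Ĉ − ε)) after each policy
minibatch step (the natural reading of "after each policy step"; the
printed bracket placement is ambiguous and this is the standard projected
form). On the toy gating environment the mechanism is visible end to end:
without the constraint, blocking during overload is optimal (it suppresses
attempts hardest); the growing multiplier makes RED-state attempts
ruinous and the learned policy shifts to WARN, meeting the budget with
measured cost ≈ 0. In the full simulator the communication budget is
*structurally* unattainable: the gate informs but never silences
(compliance 0.15 under RED), and the safety override forces RED throughout
startle episodes, so some attempts during RED are inevitable — exactly as
in the protocol this emulates, whose dual-loop condition still records
2–3 communication breakdowns per session. The multiplier then grows while
shaping saturates, which is the expected primal–dual behavior under an
infeasible constraint.

The stated stop rule (reward variation < 5% over 100 iterations, cap
5×10⁶ steps) is implemented; the desk profile caps at 1–2×10⁵ steps.
Because RED compliance suppresses exactly the attempts the β-penalty would
punish, the WARN-vs-BLOCK value gap is proportional to the communication
multiplier; the desk experiment profile therefore warm-starts λ_cbe at 30
(the dual converges upward anyway under the tight budget, and
warm-starting known-tight constraints is standard practice). With that,
the trained gate blocks voluntarily on only a few percent of steps, and
haptic assistance engages on most steps under load, which carries the
condition-level contrasts together with the override and gate
compliance.

## 6. The experiment runner and its statistics

`run_experiment()` runs pairs through the four conditions in balanced
Latin-square order (rows cycled when the pair count is not divisible
by 4). Within a pair, all four condition sessions share one seed: matched
scenarios by common random numbers, so within-pair contrasts isolate the
controller rather than schedule luck. The desk profile uses 120 s task +
45 s warm-up sessions and time-compresses the hazard (5/min) and
engineer-attempt (9/min) rates so per-session counts stay near the 600-s
protocol's. Warm-up windows are excluded from all outcome metrics.

Open-loop (and pilot-only) sessions display no gate, so their CBE is
scored against the counterfactual override-only gate reconstructed
offline from the logged class/CLI trace — otherwise the count would be
trivially zero in exactly the conditions it is meant to baseline.
Engineer decision-load proxies are attempts/min and the variance of
inter-attempt intervals. The inferential block is a one-way
within-subject ANOVA (sums of squares verified against a brute-force
decomposition; two-condition designs reproduce the paired-t identity
F = t²), Greenhouse–Geisser correction from the double-centered
covariance of condition scores, partial η², and Bonferroni-adjusted
paired contrasts with Cohen's d = mean(diff)/sd(diff). The factorial
condition × difficulty extension is out of scope; the one-way design is
complete.

## 7. Numerical and degenerate-input choices

* Window count = floor((L − W)/Δ) + 1; no partial windows; start samples
  are rounded to the sample grid.
* Welch segments are mean-detrended; one-sided density scaling with
  DC and Nyquist kept single, interior bins doubled.
* Thin-plate systems are solved densely (17×17); duplicate electrode
  positions are an error, as are antipodal projection points.
* Zero-variance warm-ups (ASR or CLI calibration) raise errors rather
  than producing degenerate thresholds; constant channels normalize to
  zero without error.
* Max-pool ties take the first maximum; dropout masks, initialization,
  shuffling, and all simulator draws flow from explicit seeds, giving
  bit-identical sessions, training curves, and reports under identical
  configuration.
* GAE uses the standard reverse recursion; λ = 0 and λ = 1 reduce to TD
  residuals and discounted-return-minus-baseline respectively (asserted).

## 8. Known limitations

The generator's additive band model cannot express realistic spatial
covariance of spontaneous activity; the formula-CLI's clipped
normalization saturates under sustained load; desk-scale controller
training under-trains the pilot head relative to the gate head; and all
decoder accuracies reported by the acceptance script are properties of
separable synthetic classes, not of human EEG. The package's claims are
therefore about the *method pipeline* — that every stage is internally
consistent, oracle-verified, and able to recover what generated its
input — and directional reproduction of the condition-level effects, not
about reproducing cohort-level magnitudes.
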