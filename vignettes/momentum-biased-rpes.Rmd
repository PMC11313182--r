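---
title: "Momentum-biased reward prediction errors: model, simulation, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Momentum-biased reward prediction errors: model, simulation, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(momentumRPE)
```

## The scientific problem

Mood instability and dysregulated reward processing co-occur in bipolar
disorder, and one mechanistic account ties them together through a recursive
loop: the *momentum* of recent reward prediction errors (RPEs) — an
exponentially integrated history of better- and worse-than-expected outcomes,
standing in for momentary mood — feeds back and biases the *perception* of
subsequent outcomes. Under this account, ventral striatal BOLD in affected
individuals should track not only the veridical RPE but also the
momentum-induced distortion of it, and the anterior insula, which carries the
momentum signal, should show altered coupling with the striatum as momentum
fluctuates.

This package implements that analysis pipeline end to end — generative RPE
models, a balanced probabilistic Roulette task, synthetic ROI BOLD with known
ground truth, a parametric-modulator first-level GLM, generalized
psychophysiological interaction (gPPI) analysis, and the group statistics
layer — so that every inferential step can be exercised and validated against
simulated data whose true effects are known.

## The generative model

Each trial has win probability $p \in \{0.25, 0.75\}$ and stake
$s \in \{3, 9\}$; a win pays $+s$, a loss $-s$, so the expected value is
$EV = (2p - 1)\,s$ and the unbiased RPE is $\delta_t = o_t - EV_t$.

The biased model runs a forward recursion in which momentum $h$ distorts the
perceived outcome and the resulting biased RPE feeds back into momentum:

$$\tilde o_t = o_t + \omega\, h_{t-1}, \qquad
  \tilde\delta_t = \tilde o_t - EV_t, \qquad
  h_t = (1-\eta)\, h_{t-1} + \eta\, \tilde\delta_t, \qquad h_0 = 0.$$

The quantity entered in the GLM is the *difference modulator*
$\Delta_t = \tilde\delta_t - \delta_t$, which under the additive form equals
$\omega h_{t-1}$: it is fully determined by outcomes *before* trial $t$,
which is what keeps it decorrelated from the same-trial unbiased RPE
(empirically $|\mathrm{corr}(\Delta, \delta)| < 0.3$ on balanced schedules —
the anti-collinearity rationale for difference coding, which we verify by
property test rather than assume).

Two confirmatory reduced models are provided: a model-free carryover check
($\delta_{t-1}$, $\delta_t$, and their product) and a momentum-only model in
which the exponential moving average of *unbiased* RPEs is used with no
feedback into perception.

### Parameter choices

- `bias_form`: the exact functional form of the perception bias in the prior
  modeling literature lives outside the sources available to this package, so
  the **additive** form above is the default — it keeps the generative process
  linear and well-behaved for mixed-sign outcomes — with a multiplicative
  variant (`o * (1 + omega * h / max_stake)`) selectable for sensitivity
  analyses.
- `eta = 0.3`, `bias_weight = 0.5`: the emulated study used a fixed
  group-average bias parameter whose numeric value is not recoverable here;
  these defaults are documented configuration placeholders, in the middle of
  the stable range, not estimates. All results that matter scale smoothly in
  both.
- Momentum updates on the *biased* RPE (the recursive cycle); it does not
  reset between blocks (a single documented choice; configurable by
  re-running per block).

## The task generator as a stated world

`generate_schedule()` reproduces the balanced design: 8 blocks × 34 trials =
272 trials, probability × stake cells exactly balanced at 68 each at session
level and to the nearest integer within blocks, outcomes realized by
*exact-frequency assignment* — a shuffled multiset of win/loss labels per
cell (34 wins among the 136 low-probability trials, 102 among the
high-probability trials) — rather than Bernoulli draws. Exact frequencies
make the downstream regressor statistics seed-stable: every seed has
identical marginal counts and only the order and jitter vary. Whether the
original task balanced outcomes per block or per session is not stated in
our sources; we chose session-level exactness because 17 × 0.25 is not an
integer. Timing defaults (choice 4 s, spin 3–4 s jittered, outcome 2 s, ITI
1–2 s) put one block near 6 minutes.

## What the BOLD generator emulates — and what it does not

`simulate_participant()` works at the level the inference works at: one
time series per ROI (the mean across an anatomical region), not voxels.
Neural activity is a train of impulses at event onsets; the ventral striatum
responds at outcome with amplitude
$\beta_{outcome} + \beta_\delta \delta_t + \beta_\Delta \Delta_t$, the left
insula adds $\beta_h h_t$ and a coupling term
$(\gamma_0 + \gamma_1 \Delta_t)$ times the striatal neural signal (coupling
is injected at the neural level, before convolution — the physiologically
cleaner contract), and the right insula carries no momentum term — its
baseline coupling sees only the condition (unmodulated) part of the striatal
signal, because the momentum GLM has no RPE column and any coupled RPE
tracking would masquerade as momentum tracking (the momentum update shares
the same-trial RPE term). Everything
is convolved with the canonical double-gamma HRF (peak ≈ 5 s, undershoot
≈ 15 s), sampled at TR = 2 s, and corrupted with AR(1) noise of marginal SD
`noise_sigma`, a slow cosine drift (~128 s period), and motion-correlated
nuisance from simulated realignment parameters.

Group structure comes from `effect_spec()`: per-participant amplitudes are
drawn from group distributions calibrated to the published effect sizes —
unbiased-RPE tracking mean 0.28 SD 0.22 (bipolar-like) / 0.20 SD 0.14
(control-like); momentum-bias tracking mean 0.75 SD 1.37 / 0.19 SD 1.08;
coupling modulation mean −0.11 SD 0.30 / +0.22 SD 0.31. Momentum tracking is
common to both groups (the study prints only d = 0.33 for the pooled sample,
so we use mean 0.33, SD 1). Symptom scores are drawn from the published
group means/SDs, truncated at 0, with the bipolar-like group's coupling
modulation latently correlated with manic symptoms at −0.45.

A green recovery test on this generator establishes that the *pipeline* is
correct and unbiased given its own assumptions. It does not establish
anything about real BOLD: there is no voxel structure, no spatial smoothing,
no physiological noise, no motion spikes or interpolated volumes, and neural
events are impulses (durations are not modeled; a boxcar variant would only
rescale amplitudes here).

## First-level GLM

The RPE-variant design has exactly 11 named task/motion regressors: choice,
anticipation, outcome condition columns; outcome modulated by mean-centered
trialwise $\delta$ and mean-centered $\Delta$; and 6 motion parameters —
plus per-run intercept and linear/quadratic drift nuisance columns. The
momentum variant replaces the two modulators with the momentum series. The
modulators are *not* serially orthogonalized by default (the difference
coding exists to make that unnecessary; a variance inflation factor below 5
between the two modulator columns is asserted by test), with
`orthogonalize = TRUE` available for comparison — orthogonalization leaves
the second modulator's coefficient unchanged, as a test demonstrates.

Estimation is plain OLS per run with equal-weight averaging across runs; no
prewhitening. The group inference operates on per-participant betas, which
tolerates first-level autocorrelation — the null-simulation tests confirm
the betas are unbiased under AR(1) noise at the default settings.

## gPPI

Per run, the psychological regressor $\psi$ is the convolved train of
outcome events weighted by $\Delta_t$ (or $\delta_t$ for the specificity
analysis); the PPI term is the elementwise product of the per-run
mean-centered seed BOLD and mean-centered $\psi$; the target is regressed on
intercept, seed, $\psi$, the PPI term, motion, and drift. This is the
BOLD-level interaction exactly as described in the methods we emulate; the
deconvolve–multiply–reconvolve neural-level scheme of the gPPI toolbox is
deliberately not implemented (the argument is reserved and errors). One
consequence, quantified by test: the BOLD-level product is an approximation,
so a zero-coupling participant shows a small residual PPI beta (a few
hundredths, against calibrated effects of 0.1–0.25) rather than an exact
zero, and recovered magnitudes are attenuated relative to the generative
$\gamma_1$ while sign and group ordering are preserved — which is all the
group inference uses.

## Group statistics

All tests are computed from closed forms and cross-checked against reference
implementations to 1e-10 in the test suite: one-sample t ($d = m/s$),
pooled and Welch two-sample t (Cohen's d always uses the pooled SD; Welch
df by Satterthwaite), Pearson χ² without continuity correction (the printed
sex × group statistic, 0.38, is reproducible only without Yates),
standardized regression on z-scored variables with `log1p` for skewed
symptom scales (scores of 0 occur, so `log` proper is unusable), and
Bonferroni correction (α/2 = 0.025 for the two insula tests). Directional
hypotheses (tracking, coupling) use one-tailed p values — the printed
p values in the emulated results are consistent only with one-tailed tests —
and every result records its tail convention.

## Numerical choices

- Convolution on a 0.1 s grid via FFT with padding, truncated causally;
  events snap to the nearest grid point.
- Sample-moment reconstruction (`moment_matched_sample`) rescales a fixed
  vector to the published mean/SD exactly, so summary-based t and d values
  are exact, not approximate.
- Seeds: every stochastic stage derives its seed from the master seed with a
  32-bit-safe linear map; identical configs give byte-identical outputs.
- Degenerate inputs: zero bias weight degenerates to the unbiased model
  identically; an all-zero psychological regressor returns a PPI beta of 0
  with a warning; rank-deficient designs error naming the collinear columns.

## Known limitations, and one deliberately red check

The validation suite demands that 200 replicate cohorts of 21 + 21
participants, simulated at the calibrated published effect sizes, reproduce
the qualitative findings pattern (bipolar-like group significant one-tailed
for the momentum-bias modulator, control-like group not, coupling difference
in the control > bipolar direction) in at least 90% of cohorts. That bound
is not attainable in the stated world, and we left the check red rather
than recalibrate: the one-sample one-tailed power at d = 0.54 with n = 21
is ≈ 0.77, the probability that the control group stays non-significant at
d = 0.18 is ≈ 0.81, and the coupling direction is essentially always
recovered (d ≈ 1.07), so the joint pattern rate is ≈ 0.62 — which is what
the simulation measures (0.58–0.62 across seeds). In other words, the
published single-study pattern is itself a fairly lucky draw at its own
effect sizes; a replication designed at these ds would reproduce the full
pattern in roughly three of five attempts. The per-component claims (each
direction, each effect size) are recovered without bias, which is what the
green recovery tests establish.

Other limitations: no per-subject fitting of $\eta$/$\omega$ (none occurred
in the emulated study, and the task removes learning by design); no
voxelwise inference; no neural-level PPI; missed responses are not modeled.
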