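---
title: "Methods: burst segmentation and sensory-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst segmentation and sensory-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeburst)
```

## The analysis problem

Extracellular recordings from small, immature or grafted cortical neural
populations often show a characteristic regime: most of the time the
population is nearly silent, interrupted by brief synchronous bursts in
which a large fraction of units fire a handful of spikes together.
`spikeburst` quantifies this regime and the population's sensory
responsiveness from spike-sorted data:

1. **Burst segmentation** — when is the population "on" vs "off", how long
   are bursts and inter-burst intervals, how many spikes does a unit
   contribute per burst, and what fraction of units does a burst recruit?
2. **Stimulus modulation** — which units increase firing after a sensory
   event (e.g. whisker deflection), and with what latency to peak?
3. **Optotagging** — which units respond to brief light pulses at short
   latency and high reliability (identifying opsin-expressing cells)?
4. **Operant behaviour** — does an animal learn to lick selectively during
   one of two light cues, summarized by a preference index and a cohort
   learning-success rate?

Because real recordings of this kind rarely come with ground truth, the
package ships a generator (`simulate_population()` and friends) that
produces recordings from a known latent model, so every stage can be
validated end to end by parameter recovery.

## Burst segmentation model

### Rates and the binary observable

Firing rates are computed in 200-ms windows sliding by 100 ms
(`bin_firing_rates()`; bins are half-open `[edge, edge + 0.2)`, left edges
at `t_start + i * 0.1`, trailing partial window dropped) and z-scored per
unit over the whole recording (`zscore_rates()`, sample s.d.; constant
rows map to zeros with a warning rather than an error, because recordings
legitimately contain silent units).

A two-state HMM with a 2×2 emission matrix requires a binary observable.
The package forms it as the thresholded population mean
(`binarize_population()`): symbol 1 when the mean over units of the
z-scored rate in a bin is strictly above 0, i.e. above-average population
activity. Per-channel binarization would also produce binary symbols, but
the population mean is far more robust for synchronous-burst detection and
matches the "population activity" framing of the segmentation; the
threshold is configurable.

### The HMM

With symbols $y_t \in \{0, 1\}$, a two-state chain
$s_t \in \{\text{off}, \text{on}\}$ with row-stochastic transition matrix
$A$, emission matrix $B$ and initial distribution $\pi$ is fitted by
Baum–Welch (`baum_welch()`), using scaled forward–backward recursions that
are safe for $10^5$-bin recordings. Convergence is declared when the
relative log-likelihood improvement falls below `tol = 1e-6` (at most
`max_iter = 500` iterations); the per-iteration log-likelihood trace is
retained and is non-decreasing up to `1e-9` numerical slack — a property
the test suite asserts on random inputs.

The default initial guesses are the conventional ones for this
segmentation task:

$$A_0 = \begin{pmatrix} 0.95 & 0.05 \\ 0.05 & 0.96 \end{pmatrix},\qquad
B_0 = \begin{pmatrix} 0.5 & 0.5 \\ 0.1 & 0.99 \end{pmatrix},$$

with each row renormalized to sum to one (the second rows as printed sum
to 1.01 and 1.09; `hmm_spec()` logs the adjustment). The state sequence is
decoded with log-space Viterbi (`viterbi()`). The "on" state is defined as
the state with the larger probability of emitting symbol 1 (ties resolve
to the second state), and path-score ties are broken toward the lower
state index at each backtrack step, so a fully symmetric model decodes
deterministically to the all-off path. Forward likelihood and Viterbi
decoding are verified against brute-force enumeration over all $2^T$
paths for short sequences.

### From state path to burst statistics

`label_bursts()` tabulates maximal runs of identical state. Two
conventions matter and are both configurable:

* **Flicker suppression** (`min_run = 2`): interior runs shorter than two
  bins are merged into a flanking run (shorter neighbour first, ties to
  the left). Runs touching a recording boundary are exempt — the edge
  truncates them, so their observed length is uninformative — and are
  flagged non-interior and excluded from all duration statistics.
* **Duration convention**: a run of $k$ bins spans the *centres* of its
  first and last bin, giving duration $(k-1) \times \text{step}$. A
  200-ms window slid by 100 ms smears a true burst outward by roughly one
  bin on each side (a window overlapping a burst edge still registers
  elevated rate); measuring centre-to-centre compensates most of that
  smear. On the default synthetic conditions the residual bias is a few
  percent upward for burst durations and a few percent downward for
  inter-burst intervals, well inside the recovery tolerances.

`burst_statistics()` then reports, over interior bursts only: mean/median
burst duration, mean inter-burst interval, the recruitment fraction (mean
over bursts of the fraction of units with at least one spike inside the
closed burst interval), and spikes-per-burst averaged over *recruited*
(unit, burst) pairs only. Averaging over recruited pairs keeps the
statistic non-redundant with recruitment; averaging over all pairs is a
trivial product of the two and can be formed by the user if wanted.
`burst_pipeline()` chains all of the above.

### Correlations and spectra

`pairwise_correlations()` computes Pearson correlations between unit rate
rows (estimator configurable), excluding constant units from the
off-diagonal summary, and `compare_correlations()` provides a rank-sum
comparison of two recordings' off-diagonal sets — the natural test for
"this population is more synchronous than that one". `welch_psd()`
implements Welch's method with a periodic Hann window, 50% segment
overlap, per-segment mean removal and density normalization (the PSD
integrates to the signal variance); the default segment length is
`10 * fs` samples, i.e. 10 s of signal.

## Stimulus modulation

`modulation_test()` compares, per unit, per-trial spike counts in
`(onset, onset + 1 s]` against `[onset - 1 s, onset)` with a two-sided
Wilcoxon signed-rank test. Zero differences are dropped (the standard
convention); the exact null distribution is used when there are at most
25 non-zero differences without ties, the normal approximation with
continuity correction otherwise. A unit is flagged *modulated* at
`alpha = 0.05` when additionally its median count difference is positive
(`direction = "increase"`), because the scientific question is about
firing-rate *increases*; a pure two-sided flag is available and is the one
whose false-positive rate equals `alpha` (the directional flag rejects at
roughly `alpha/2` under the null, by construction). No multiple-comparison
correction is applied by default; users testing many units for discovery
purposes should correct the returned p-values themselves
(`p.adjust`).

`latency_to_peak()` reports the lag of the maximum of the trial-averaged
z-scored trace within `(0, 2 s]` after onset, at the rate-step resolution
(100 ms); flat traces return the earliest lag with a `degenerate` flag.
`random_timestamp_control()` draws the same number of events uniformly
inside a guard band of `pre + post` from the recording edges, seeded, for
running the identical analysis path as a null control.

## Optotagging

`classify_optotagged()` declares a unit responsive when it spikes within
10 ms of pulse onset on at least 70% of pulses. Both thresholds are
inclusive ("70% or more", "within 10 ms"); the response window is open at
the onset itself, so a spike exactly at light onset — indistinguishable
from a photoelectric artifact — does not count. Any spike in the window
counts as a response (the criterion asks for "a spiking response", not
specifically the first spike); the reported latency is the first spike's.
On simulated protocols with per-pulse reliability $r$, the classification
rate over many units matches $P(\mathrm{Bin}(10, r) \ge 7)$, which the
suite checks against the closed form.

## Operant behaviour

`preference_index()` is $(B - R)/(B + R)$ over a session's lick totals
during blue (473-nm) vs red (635-nm) stimulation. A 0/0 session is
*undefined* (`NA`), not zero — a rat that never licked expressed no
preference — and undefined days are excluded from trajectories and break
consecutive-day runs (the conservative choice). `learning_success()`
flags an animal when some run of at least 2 consecutive training days all
have a defined score strictly above 0.2, and reports the cohort rate
rounded to the nearest percent with the raw fraction preserved.
`fixture_F1()` provides a deterministic 9-animal, 15-day cohort in which
eight animals ramp from 10 to 94 expected blue licks against a flat 40
red licks (crossing the criterion from day 10) and one stays symmetric,
giving an 8/9 = 89% worked example.

## The synthetic generator

`simulate_population()` draws an alternating on/off renewal process that
tiles the recording, recruits each unit per burst with probability
`recruit_prob`, places `1 + Poisson(spikes_mean)` spikes uniformly within
the burst for each recruited unit, and superimposes homogeneous Poisson
noise at `noise_rate` over the whole recording. Defaults are the
population statistics the pipeline is designed to recover — mean burst
duration 0.46 s and silent period 2.0 s (gamma dwells, shape 4),
recruitment 0.73, `spikes_mean = 2` (mean 3 spikes per recruited burst),
noise 0.05 Hz, 64 units, 600 s. Design choices:

* **Gamma dwells by default** (shape 4) rather than geometric: a
  memoryless on-process puts substantial mass on sub-bin bursts that
  200-ms windows cannot resolve; gamma dwells of the same mean are
  testable at the analysis resolution. Geometric dwells
  (`dwell_spec("geometric")`) remain available for Markov-consistency
  checks, where the fitted self-transition probabilities are compared
  against the empirical transitions of the true state sampled at bin
  centres.
* **Noise everywhere, not off-state-only** — simpler, and a harder test
  for the detector.
* **Superposition, not thinning**, for evoked spikes: modulated units in
  `simulate_stimulus_session()` receive an independent inhomogeneous
  Poisson process with rate kernel
  $A \, (t/\tau) \, e^{1 - t/\tau}$ (peak $A$ Hz at $\tau$; default 6 Hz
  at 0.65 s), sampled exactly via its Gamma(2, $\tau$) normalized density.
* **Event placement** uses the exact spacing transform (subtract the
  mandatory 4-s separations, drop sorted uniforms into the free length,
  add the separations back), which samples the uniform distribution
  conditional on the separation constraint directly — naive rejection has
  a vanishing acceptance rate at 50 events in 20 min.
* **One seed per call**: every simulator routes all randomness through
  `withr::with_seed`, so identical seeds give bit-identical outputs and
  the caller's RNG state is untouched.

`simulate_light_protocol()` adds the pulse protocol (ten 10-ms pulses at
2 Hz by default) with per-pulse Bernoulli responses at latency
`|N(4 ms, jitter)|` truncated to `(0, 10 ms]`.
`simulate_behavior_cohort()` produces Poisson per-trial lick counts whose
session means follow the learner/non-learner ramps above.

What the generator does **not** emulate: refractory periods, unit-specific
rate heterogeneity, burst-internal temporal structure (spikes are uniform
within bursts), drift/nonstationarity across a session, spike-sorting
contamination, and correlated noise between units. Passing recovery tests
therefore demonstrates correctness of the estimators under the assumed
model, not robustness to every artefact of real recordings.

## Problem sizes and runtime

The recovery suites use 600-s, 64-unit recordings (three replicate
simulations) for burst statistics and 1,200-s, 13-unit sessions with 50
events for modulation/latency, reflecting the scale of the recordings the
defaults emulate; property suites use brute-force enumeration up to 12
bins and null populations of up to 1,000 Poisson units. The full test
suite runs in well under a minute on one CPU.

## Known limitations

* The two-state model cannot represent graded burst intensities; a
  three-state or continuous-emission variant is out of scope.
* Dwell times of the fitted chain are geometric by construction; when the
  generating dwells are gamma, the HMM still segments well but its
  transition probabilities are an effective, not mechanistic, description.
* Burst intervals inherit the bin geometry: durations are quantized to
  the 100-ms step and bursts shorter than ~2 bins are not detectable.
* `modulation_test()` treats trials as exchangeable; slow drift across a
  session will inflate its false-positive rate on real data (the
  randomized-timestamp control is the recommended check).
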