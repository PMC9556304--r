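# spikeburst

Analysis of population spike-train recordings that exhibit synchronous
bursting — the regime typical of immature or grafted cortical tissue
recorded in vivo, where a mostly silent population is punctuated by brief
bursts that recruit most units at once. The package takes spike-sorted
unit data (plain tables or phy-style sorter output) plus event and
behaviour logs, and answers four questions:

* **When is the population bursting?** Firing rates in 200-ms windows
  sliding by 100 ms are z-scored per unit, the population-mean trace is
  binarized at z = 0, and a two-state hidden Markov model — fitted by
  Baum–Welch from the standard initial guesses
  `A = [0.95 0.05; 0.05 0.96]`, `B = [0.5 0.5; 0.1 0.99]`
  (row-normalized) and decoded by Viterbi — labels each bin "on" (burst)
  or "off" (inter-burst interval). Burst tables report durations
  (`(k−1) × step` for a k-bin run), inter-burst intervals, spikes per
  recruited (unit, burst) pair, and the per-burst recruitment fraction.
* **Which units respond to a sensory stimulus?** Per-trial spike counts
  1 s after vs 1 s before each event are compared with a Wilcoxon
  signed-rank test (p < 0.05 and a positive median shift flags a unit as
  modulated), and response latency is the time to the peak of the
  trial-averaged z-scored trace within 2 s. Randomized-timestamp
  controls run through the identical path.
* **Which units are optotagged?** A unit is light-responsive when it
  spikes within 10 ms of pulse onset on ≥ 70% of pulses.
* **Did the animal learn?** Per-session preference index
  `(blue licks − red licks) / (blue + red)`; an animal succeeds when its
  score exceeds 0.2 on ≥ 2 consecutive training days, and the cohort
  success rate is the percentage of such animals.

A synthetic-data generator with full ground truth (latent state
intervals, recruited sets, modulated and tagged units) makes every stage
testable by parameter recovery without any animal data.

## Worked example

```r
library(spikeburst)

# a 600-s, 64-unit recording with known ground truth:
# ~0.46-s bursts, ~2-s silent periods, 73% recruitment,
# 1 + Poisson(2) spikes per recruited burst, 0.05-Hz noise
cfg <- synth_config(duration = 600, n_units = 64, seed = 1)
sim <- simulate_population(cfg)
sim$spikes
#> <spike_train_set> 64 units, 38349 spikes, [0, 600] s

result <- burst_pipeline(sim$spikes)
result$stats
#> <burst_stats> 260 interior bursts
#>   mean duration: 0.4723 s
#>   mean inter-burst interval: 1.63 s
#>   spikes per recruited (unit, burst): 2.909
#>   recruitment: 0.7329

round(result$model$transition, 3)
#>       [,1]  [,2]
#> [1,] 0.942 0.058
#> [2,] 0.174 0.826

pairwise_correlations(result$rates)$mean_offdiag
#> [1] 0.3733...
```

The pipeline recovers the generative statistics: mean burst duration
0.47 s (truth 0.46), recruitment 0.733 (truth 0.73), 2.9 spikes per
recruited pair (truth 3). The fitted off-state self-transition 0.942 per
100-ms step corresponds to a ~1.7-s mean silent period, and the shared
latent state makes the units strongly correlated (mean pairwise
correlation 0.37; independent Poisson populations give ≈ 0).

The behavioural criterion on the deterministic worked-example cohort:

```r
traj <- session_preferences(fixture_F1())
learning_success(traj)$rate_percent
#> [1] 89
```

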