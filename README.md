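# aqifnet

Deterministic adaptive spiking networks and the machinery to fit them to
multi-neuron cortical recordings.

Cortical populations move between a *desynchronized* regime of steady,
weakly correlated firing and a *synchronized* regime of population-wide
alternations between active **up states** and silent **down states**.
`aqifnet` implements a minimal, fully deterministic network model that
spans this whole spectrum, together with the summary statistics, cost
function and optimizers needed to match the model to a recording, the
stimulus-driven analyses (noise correlations, frequency tuning,
Poisson-likelihood decoding), recording-side state analyses (spike-waveform
classification, LFP synchrony, running-bout segmentation), and
synthetic-data generators that replace in vivo recordings in closed-loop
tests. It is aimed at computational and systems neuroscientists who want a
desk-scale, scriptable implementation of this model family.

## The model

Each of N = 512 quadratic integrate-and-fire neurons obeys

    tau_m dV_i/dt = (V_i - E_L)(V_i - V_th)
                    - gE_i (V_i - E_E) - gI (V_i - E_I) - gA_i (V_i - E_A)

with a spike and reset to `V_reset = 0.9 V_th` whenever `V_i > V_th`, and
`V` clamped at `E_I` for numerical stability. Three conductances drive the
voltage, each following `tau dg/dt = -g + drive`:

* **Excitation** `gE_i`: recurrent spikes through a sparse random weight
  matrix `J` (connection probability 5%, weights uniform on `(0, wE]`),
  a constant tonic input `b_i = b0 + Exp(b1)`, and any external stimulus
  drive (`tau_E` = 5.1 ms).
* **Global supralinear inhibition** `gI`: every neuron receives
  `wI (exp(c * n_spikes) - 1)` of the previous step's population spike
  count (`c` = 0.25, `tau_I` = 3.75 ms). The exponential supralinearity
  shifts the excitation/inhibition balance toward inhibition whenever the
  network is strongly driven.
* **Spike-frequency adaptation** `gA_i`: incremented by the neuron's own
  spikes with strength `wA` (`tau_A` = 375 ms); this slow self-inhibition
  terminates up states and paces the alternation.

Integration is forward Euler at `dt` = 0.75 ms and bitwise deterministic:
all trial-to-trial variability is intrinsic chaotic dynamics, not injected
noise. The five free parameters `(wI, wA, wE, b1, b0)` are fit to a
recording by minimizing a three-term normalized cost comparing the mean
pairwise correlation, the sorted distribution of multi-unit activity (MUA,
15 ms bins), and the MUA autocorrelation function, via either a cached grid
search with neighborhood smoothing or a Barker-rule MCMC sampler with
pooled restarts. Two robustness variants are included: slow NMDA/GABA_B
conductance channels, and a 144-cluster network with explicit spiking
inhibitory neurons.

## Worked example

```r
library(aqifnet)

p <- model_params()          # the up/down-state example point
sim <- simulate_network(p, duration_s = 60, seed = 1)
r <- subsample_neurons(bin_raster(sim, 15), k = 50, seed = 2)
summary_stats(r)
```

```
aqif_stats: rate 10.20 sp/s/neuron, corr 0.013, silence 25.1%, ACF decay 54 ms
```

At these parameters a quarter of all 15 ms bins are completely silent
(down states) while the mean rate stays above 10 spikes/s/neuron (up
states), and the MUA decorrelates over tens of milliseconds. The dynamics
are chaotic: re-running the same deterministic simulation with one extra
spike inserted into one neuron decorrelates the population trajectory
within a few seconds,

```r
pert <- simulate_network(p, duration_s = 60, seed = 1,
                         inserted_spikes = data.frame(neuron = 7,
                                                      time_ms = 6000))
m1 <- compute_mua(bin_raster(sim, 15))
m2 <- compute_mua(bin_raster(pert, 15))
cor(m1[68:400], m2[68:400])   # the 5 s after the insertion
#> 0.158
```

Increasing the inhibitory feedback `wI` desynchronizes the network: percent
silence, pairwise correlations, evoked noise correlations, and tuning
widths all fall as `wI` rises (`parameter_sweep()`, `simulate_evoked()`,
`tuning_width()`). Fitting is driven by `summary_stats()`,
`make_normalizers()`, `grid_fit()` / `mcmc_fit()`, and
`refit_transition()` for one- and two-parameter state-transition refits.

A thin command-line wrapper is installed with the package
(`inst/scripts/aqifnet-cli`) with `simulate`, `stats` and `gen`
subcommands operating on CSV/JSON files.

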