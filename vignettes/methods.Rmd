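---
title: "Model, statistics and fitting choices in aqifnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, statistics and fitting choices in aqifnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aqifnet` simulates a deterministic network of conductance-based quadratic
integrate-and-fire neurons with global supralinear inhibitory feedback and
spike-frequency adaptation, and fits its five free parameters to
multi-neuron recordings through summary statistics. This vignette is the
package's account of the numerical contract, the parameter meanings, the
open design choices we had to settle, and what the synthetic-data tests do
and do not establish.

## The network and its integration contract

The subthreshold voltage of neuron $i$ follows

$$\tau_m \dot V_i = (V_i - E_L)(V_i - V_{th})
  - g_{E,i}(V_i - E_E) - g_I (V_i - E_I) - g_{A,i}(V_i - E_A),$$

with $E_L = 0$, $V_{th} = 1$, $E_E = 2$, $E_I = E_A = -0.5$, reset to
$V_{reset} = 0.9$ on threshold crossing, and all conductances obeying
$\tau \dot g = -g + \text{drive}$. Euler integration at $dt$ = 0.75 ms.

Several aspects of this contract were genuinely open and are fixed as
follows:

* **Sign of the quadratic.** We use the standard QIF orientation: a stable
  rest near $E_L$, an unstable point near $V_{th}$, and a saddle-node at
  excitatory drive $g_E = 3 - 2\sqrt{2} \approx 0.172$. This orientation
  is the only one under which silence is a stable collective state, a few
  neurons in the exponential tail of the tonic input act as pacemakers
  that re-ignite up states, and the published parameter ranges produce the
  full spectrum from tonic firing to up/down alternation. With the
  opposite orientation every neuron becomes a perpetual oscillator and a
  silent network can never restart at these tonic-input values.
* **Impulse scaling.** Spike-driven terms (recurrent impulses $J s$, the
  inhibitory population term $w_I(e^{c\sum s} - 1)$, adaptation $w_A s$)
  enter the conductance update through the same $dt/\tau$ Euler factor as
  the decay and the continuous drives — i.e., the printed differential
  equations are integrated literally. Applying impulses at full amplitude
  instead makes mean single-spike excitatory increments of $w_E/2 \approx
  2.25$, large enough that a population volley jumps voltages from the
  $E_I$ clamp across threshold within one step; because both the
  inhibitory and the adaptation current vanish exactly at the clamp
  (their reversal equals the clamp level), nothing can arrest the
  resulting two-step runaway oscillation. The $dt/\tau$ convention is
  stable for every parameter set in the fitting ranges.
* **Synchronous update.** A neuron spikes when its post-update voltage
  exceeds $V_{th}$; its impulses act on the *next* step's conductances.
  Inserted spikes are realized by forcing the voltage above threshold at
  the stated step, so reset and all couplings follow naturally.
* **Rectification.** Voltages are clamped at $E_I$ after every update,
  read as the "activation potential of the inhibitory conductance"; this
  also bounds the state space.
* **Initial state and burn-in.** Unless supplied, $V \sim U(E_L,
  V_{reset})$ from a stated seed with zero conductances, and the first 5 s
  (configurable) are discarded — the adaptation timescale is 375 ms, so
  5 s is far beyond the transient.

The integrator is a single C++ core shared by the base model, the slow
NMDA/GABA$_B$ variant (increments are 4% / 2% of the corresponding fast
increment amplitudes, decaying with $\tau$ = 100 ms, so the slow excitatory
channel injects $0.04 \times 100/5.1 \approx 0.78$ of the fast integrated
conductance), and the clustered variant (explicit inhibitory neurons,
conductance-based synapses with reversal $E_I$, two membrane time
constants, adaptation on excitatory cells only, no global term). Setting
the variant-specific strengths to zero reproduces the base model bitwise.

One consequence of the pacemaker mechanism deserves note: the expected
number of neurons with tonic drive above the saddle-node is only a few per
512 at the up/down example point, so a small fraction of random tonic-input
realizations contain none and stay silent. The fitting machinery treats
such degenerate parameter/realization combinations as maximal-cost points
rather than errors.

## Parameters

| name | meaning | default | fitting range |
|------|---------|---------|---------------|
| `wI` | global inhibitory feedback strength | 0.22 | 0.01–0.4 |
| `wA` | adaptation strength per spike | 0.80 | 0.4–1.45 |
| `wE` | upper bound of uniform synaptic weights | 4.50 | 2.5–5.0 |
| `b1` | tonic input spread (exponential mean) | 0.03 | 0.005–0.10 |
| `b0` | tonic input baseline | 0.013 | 0.0001–0.05 |

The defaults are the up/down-state example point. All other constants
(time constants, reversals, `c` = 0.25, `N` = 512, 5% connectivity,
`dt` = 0.75 ms) are fixed. Increasing `wI` monotonically reduces percent
silence, pairwise correlations, evoked noise correlations and tuning
width; increasing `wA` lengthens the MUA autocorrelation decay.

## Summary statistics

The fitted statistics are computed on a random 50-neuron subsample of the
network to replicate the small-sample bias of ~50-neuron recordings:

* **MUA**: summed spikes over neurons in 15 ms bins.
* **ACF**: autocorrelation of the mean-subtracted MUA, normalized so the
  zero-lag value is 1 (the axes of decaying-to-zero ACFs require both);
  default maximum lag 600 ms, 900 ms during fitting. The decay timescale
  is the $T$ of a least-squares fit of
  $a\,e^{-\tau/T}\cos(\tau/(2\pi t_{period}))$; a pure exponential drives
  $t_{period}$ to its large bound without error. For awake-style data a
  zero-phase 4th-order Butterworth high-pass at 1 Hz removes
  tens-of-seconds drifts first.
* **Sorted MUA distribution**: MUA values sorted ascending, resampled to
  100 quantile rank bins so recordings of different lengths share a grid.
* **Mean pairwise correlation**: Pearson correlation of 15 ms counts over
  all unordered pairs; zero-variance units are excluded and counted. The
  printed covariance-style definition of residual correlations is likewise
  normalized to a Pearson correlation (a raw-covariance mode exists behind
  `pearson = FALSE`).
* **Noise correlations**: residual method (subtract each neuron's
  trial-averaged response) and shuffle method (total minus signal
  correlation, trial order shuffled independently per neuron and time bin,
  100 shuffles averaged — the shuffle count is our choice). The two agree
  within sampling error on constructed data.

## The cost and the optimizers

For recording $n$ and parameters $\theta$:
$\text{Cost} = \text{Cost}_c + \text{Cost}_m + \text{Cost}_a$, where the
correlation term is normalized by the variance of mean correlations across
the recording collection, and the MUA-distribution and ACF terms by the
squared distance of the recording to the collection mean — each term is 1
when the model does no better than the average recording. Degenerate
normalizers raise errors rather than divide silently; when fitting a
single synthetic recording the normalizing collection is a bundled cohort
of at least 8 surrogate recordings.

`grid_fit()` minimizes the cost over a cached full-factorial grid after
averaging each point with its `k` = 10 nearest neighbors in axis-index
space (axes are standardized because parameter units are incommensurable).
`mcmc_fit()` samples the same grid lazily with one-axis neighbor
proposals, the Barker acceptance rule
$1/(1 + e^{(\text{Cost}_{new} - \text{Cost}_{old})/T})$, restarts every 50
samples from the pool of already-sampled points weighted by
$e^{-\text{Cost}/T}$, and optional pooling across recordings. The default
temperature $T$ = 0.3 with an optional geometric annealing schedule is our
choice; the acceptance rule and restart policy are part of the method.

**Desk-scale problem sizes.** The reference implementation of this
procedure sampled on the order of $10^6$ grid points at 900 s each on GPU
hardware. This package targets a single CPU, so the default grid is a
4-point-per-axis factorial (1024 points) with 45–60 s cache simulations,
and the recovery experiments use 300 s data simulations. Two consequences
are documented rather than hidden:

* A grid point defines the model *including* its quenched randomness, so
  the cache and recovery protocol use one canonical
  connectivity/tonic/subsample realization per $\theta$ (as in a
  one-realization-per-grid-point sweep); recovery data are independent
  chaotic trajectories from different initial states. Averaging
  statistics over several realizations (`grid_evaluator(n_reps = ...)`)
  is available for fitting real recordings, where the recording's own
  realization is unknown.
* Neighborhood smoothing presumes neighbors are close in parameter space.
  On a 4-point axis a neighbor is a third of the range away and smoothing
  demonstrably degrades recovery (97% to 78% of parameters within one
  grid step in our experiments), so the recovery protocol evaluates the
  raw cost (`k_smooth = 0`) while `grid_fit()` keeps `k = 10` as its
  documented default for dense grids.

With this protocol, 97% of parameters are recovered within one grid step
across 12 planted points in the bundled experiment (the acceptance test
requires at least 80%).

`split_half_variance()` computes the noise ceiling from interleaved 4 s
segments; vector statistics per recording, scalar statistics pooled across
a cohort (the per-recording variance of a scalar is undefined).
`refit_transition()` enumerates all 5 single-parameter and 10
parameter-pair refits over sub-grids that always include the stationary
value, so the no-change model is nested in every option and pair costs
never exceed single costs.

## Stimulus-driven analyses

External input is built from frequency-grouped trial-averaged source
PSTHs: model neurons are assigned to groups in contiguous equal blocks
(tonotopic fan-out is not modelled), each summing 10 randomly chosen
channels of its group, and the pooled drive is affinely rescaled (gain +
offset, clipped at zero) to mean 0.06 and maximum 0.32 — a pure gain
cannot satisfy both targets in general, and constant drives make the map
infeasible and raise an error. Evoked trials are consecutive stimulus
repetitions within one continuous deterministic session, so trial-to-trial
variability is entirely intrinsic history dependence; an
independent-initial-state mode exists. Tuning curves share one wiring and
one affine map across tones, and widths are full width at half maximum by
linear interpolation. The decoder models each neuron-bin as Poisson with
the empirical training mean floored at $1/(2\,n_{train})$, uses stratified
5-fold cross-validation, and reports percent error.

Monotone suppression of evoked noise correlations by inhibition is tested
at 330 trials per point over five base parameter sets; because the
correlations are quenched to a zero floor by mid-range inhibition, where
consecutive estimates differ by about $\pm 10^{-3}$ in either direction,
the monotonicity check counts only increases above 10% of a sweep's
dynamic range and additionally requires the final value to fall below a
quarter of the initial one.

A limitation found with the synthetic stimuli: the *decoding* benefit of
inhibition is regime dependent in this implementation. At
moderate-excitation parameter sets stronger inhibition cuts decoding error
(68% to 41% in the bundled test), but at the up/down example point the
evoked-rate suppression outweighs the variability quenching and error does
not fall. Evoked noise correlations and tuning widths decrease with
inhibition at every base parameter set we tested.

## State analyses

Waveform classification smooths the mean waveform with a Gaussian of
$\sigma$ = 0.5 samples (truncated at $\pm 4\sigma$), takes the global
trough and the first subsequent local maximum, and applies strict
inequalities — awake: FS $<$ 0.6 ms, RS $>$ 0.8 ms; anesthetized: FS $<$
0.4 ms, RS $>$ 0.65 ms — with boundary values unclassified. The LFP
spectrogram uses Hamming-windowed quadrature pairs on an integer 1–100 Hz
grid, window length two periods of the evaluated frequency clipped to
[2/30 s, 1 s]; kernels are amplitude-normalized so power is comparable
across the adaptive-resolution axis (the two-period window implies a main
lobe of half-width about $f$, which bounds the attainable frequency
separation). The synchrony index is the log low/high band-power ratio:
3–10 Hz vs 11–96 Hz excluding 45–55 Hz in stimulus-locked 500 ms windows,
or 1–10 Hz vs 11–100 Hz in sliding 10 s windows for
urethane-style recordings — the two band conventions are kept as distinct
modes. Running bouts: 0.5 s median filter, threshold at 1/100 of the
trace SD, uniform runs of at least 5 s, 1 s trimmed from each end.
Evoked-response removal subtracts each neuron's mean stimulus response
(minus its spontaneous rate) trial-wise, drops units below 0.1 spikes/s,
and equalizes mean rates to the population mean.

## Synthetic data

The generators produce every input the pipelines need, with ground truth
attached. Surrogate recordings are doubly stochastic: a two-state
semi-Markov process (gamma dwell times — the shape parameter decouples the
ACF shape from occupancy, which a Markov chain cannot) modulates
per-neuron Poisson rates, optionally multiplied by a shared slowly varying
gain that controls pairwise correlations. Cohorts span rates of roughly
0.5–10 spikes/s, correlations 0–0.3 and silence 0–80%, so the fitting
normalizers are well conditioned. Source PSTHs have Gaussian tuning over
log-frequency (tone mode) or formant-like band envelopes with a shared
syllabic modulation (speech mode); state cohorts couple an FS/RS gain
switch, state-dependent low-frequency LFP power, bimodal waveform widths
and running bouts into one consistent bundle.

What these tests do **not** establish: the generators are Poisson given
their latent processes, so they cannot probe deviations from
Poisson-conditional variability, electrode artifacts, spike-sorting
errors, or non-stationarities slower than the simulated sessions; passing
the closed-loop tests shows the estimators recover *planted* structure of
the modelled kinds, not that real recordings satisfy those models.

## Problem sizes used by the bundled tests

Simulations in the unit tests run 2–60 s; the recovery experiment uses a
1024-point grid at 45 s per point plus twelve 300 s recordings; the
transition-refit experiment uses 60 s evaluations and ten 300 s running
recordings; evoked experiments use 25–30 trials of 1.2–1.75 s stimuli.
These sizes keep the full suite within tens of minutes on one CPU while
leaving every acceptance margin intact.
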