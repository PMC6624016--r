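---
title: "Extracting cyclic-flux manifolds from noisy activity time series"
author: "fluxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting cyclic-flux manifolds from noisy activity time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxmap)
```

## The model

Recordings of many neurons over time (for example z-scored calcium
$\Delta F/F$ traces at a few frames per second) are treated as observations
of a noisy dynamical system at steady state. At steady state a system can
either be purely diffusive, or it can carry deterministic, divergence-free
*cyclic fluxes* — closed loops in phase space along which the state
circulates. fluxmap extracts those loops and summarizes the dynamics with
just two macroscopic variables: which loop the system is on ($\alpha$) and
where along it ($\theta$).

The pipeline is:

1. **Preprocess** — Gaussian smoothing (SD 1 frame), per-neuron z-scoring,
   and a central-difference time derivative of the z-scored signal.
2. **Delay embedding** — the state at frame $t$ concatenates activity and
   derivative snapshots at lags $0, \tau, \dots, 5\tau$ (defaults
   $\tau = 10$ frames, 5 delays), giving $d = 2\,n_{\mathrm{neurons}}(n_{\mathrm{delays}}+1)$
   dimensions; 15 neurons with 5 delays yield a 180-dimensional state.
   $\tau$ is chosen where the trace autocorrelation first crosses zero
   (`estimateDelay`).
3. **Asymmetric diffusion kernel** — row $t$ of the transition matrix
   places Gaussian mass $\exp(-\|D_{t+1}-D_j\|^2/2\sigma^2)$ on the
   neighborhood of the *next* observed point (the successor plus its 11
   nearest neighbors by default), then row-normalizes. Centering the kernel
   forward in time is what makes the matrix asymmetric and its spectrum
   complex; a symmetric kernel has a real spectrum and can express only
   diffusion.
4. **Spectral phase and flux identity** — the phase of each state is the
   componentwise argument of the right eigenvector belonging to the
   largest-modulus complex eigenvalue; loops are identified by
   maximum-modularity (Louvain) clustering of the maximal time-lagged
   correlations between rows of the densified matrix $M^N$.
5. **Manifold binning** — states are binned by ($\theta$, $\alpha$) into
   Gaussian phase bins ($\Delta\theta = 0.05$ rad, so 126 bins per flux);
   each bin stores mean embedded activity, mean raw-neuron activity,
   its behavioral-state distribution, occupancy, and the empirical
   bin-to-bin transition matrix.
6. **Simulation and forecasting** — the bin-level Markov chain is simulated
   (one step = one acquisition frame) and mapped back to activity (bin
   means, or sampled member snapshots) and behavior (sampled or modal);
   dwell-time statistics, transition-time forecasts, and the dwell-only
   null model quantify what position on the manifold predicts.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `sigmaFrames` | 1 frame | smoothing SD; far below trace autocorrelation times |
| `tau` | 10 frames | embedding delay (first autocorrelation zero) |
| `nDelays` | 5 | extra lags; results robust to this choice |
| `kNeighbors` | 12 | kernel neighborhood (successor + 11 nearest) |
| `localWindow` | 12 frames | window of the local SD $\sigma_l$ in the bandwidth |
| `minFrac` | 0.25 | row fill required of the densified matrix $M^N$ |
| `deltaTheta` | 0.05 rad | phase bin spacing and bin SD |
| `minCount` | 5 | occupancy below which a bin is "unassigned" |
| `medianWindow` | 11 frames | behavior median filter before dwell statistics |
| `boutGap` | 30 frames | forward gap tolerated inside a backing bout |
| `mergeRate` | 0.02/frame | inter-cluster flow above which clusters are one flux |

## Numerical choices

**Bandwidth self-reference.** The kernel bandwidth
$\sigma^2 = \sigma_l(D_{t+1})\sigma_l(D_t)\langle k \rangle$ contains the
mean of the kernel it normalizes. The default `two_pass` resolution
computes a provisional kernel with $\sigma_0^2 = \sigma_l(D_{t+1})\sigma_l(D_t)$,
updates $\sigma^2 = \sigma_0^2 \langle k_0\rangle$, and re-evaluates once;
`fixed_point` iterates the update to a $10^{-6}$ relative tolerance (at most
50 iterations). Both agree closely in practice and exactly in the small-
bandwidth limit. $\sigma_l$ uses the population SD convention. If
$\sigma^2 = 0$ (locally constant data) the row degenerates to its observed
successor, with a warning.

**Recording-final states.** The last state of each recording has no
observed successor. By default it receives a self-loop (`terminal =
"absorb"`), which keeps the matrix exactly row-stochastic so the leading
eigenvalue is exactly 1; `terminal = "drop"` leaves the row empty instead,
which is the pure form of the deterministic limit (`kNeighbors = 1`
reproduces the observed sequence as an exact superdiagonal matrix). Final
states are excluded from densification and clustering — an absorbing state
would otherwise soak up all probability mass under exponentiation — and
inherit their predecessor's labels.

**Leading eigenpair.** Dense LAPACK eigendecomposition up to 2500 states;
above that, a deterministic (RNG-free) orthogonal subspace iteration with
explicit residual checks, falling back to the dense path when it does not
converge. Phases from the conjugate eigenvector are negated; orientation is
fixed so the median circular phase increment along observed time is
positive.

**Flux clustering.** Louvain modularity clustering is applied to the
pairwise maximal circular-lag row correlations (negative similarities
clipped to zero), best of 10 seeded restarts. On ring-like graphs
modularity optimization characteristically over-partitions a single loop
into phase arcs, so clusters are then merged by flow: arcs of one loop
exchange probability mass every revolution (of order $\omega/2\pi$ per
frame), whereas genuinely distinct loops communicate only through
occasional junction hops (an order of magnitude rarer). The default
threshold, 0.02/frame, sits between those scales. After clustering, the
leading cyclic mode and phases are recomputed within each flux's own
re-normalized submatrix, because one global eigenmode cannot phase two
disjoint loops coherently.

**Phase geometry.** All phase arithmetic is circular on $(-\pi, \pi]$;
bins are laid uniformly with spacing $2\pi/\lceil 2\pi/\Delta\theta\rceil$
and assignment is by circular Gaussian likelihood with ties to the lower
bin index. The total bin count is data-driven (bins per flux times the
number of fluxes, unoccupied bins flagged) rather than fixed, reproducing
the construction rule rather than any dataset-specific constant.

**Categorical median filter.** The behavior median filter is implemented as
a sliding majority vote with ties keeping the incumbent label. For the
two-label forward/backward case this is exactly a median filter on label
codes, and it remains well defined for more labels. It also absorbs
"unassigned" emissions from sparsely occupied transition bins, which
otherwise fragment dwell runs.

**Dwell and bout conventions.** Dwells are contiguous runs after
filtering, in frames; a backing bout spans from the first backward run to
the last backward run of a group separated by forward interruptions of at
most 30 frames. KL divergences between dwell distributions are computed in
nats on kernel-smoothed histograms over the union support, minimized over
40–200 bins (information quantities are binning-sensitive; the scan
removes that arbitrariness conservatively), with an additive $10^{-12}$
floor against empty bins.

## What the synthetic generators emulate

`simulateTwoNeuron` integrates a two-unit excitable network (fast
excitatory A, slow inhibitory B, logistic activations, weights
$w_{AA}=8, w_{AB}=-6, b_A=-0.34, w_{BA}=16, w_{BB}=-2, b_B=-2.5$,
$\tau_B = 6$) by forward Euler at $dt = 0.01$ with per-step Gaussian noise
of SD 0.1. Two points are deliberate: the noise is added per step as
written, without $\sqrt{dt}$ scaling, so its effective magnitude is
$dt$-dependent; and the SD-versus-variance reading of the noise parameter
is configurable (`noiseAsVariance`), SD being the default interpretation.
Initial state (0.5, 0.5) with a 1000-step burn-in.

`simulateNoisyLoops` rotates a latent planar point around one of several
disjoint circles at fixed angular speed, adds latent Gaussian noise, and
mixes linearly into the observation channels; when several loops exist the
trajectory hops at a junction phase with probability 0.2 per passage —
occasional by design, so that the system completes several revolutions per
visit and the ground-truth loop identity is well defined away from hops.
The frames whose embedding window straddles a hop are genuinely ambiguous;
they bound achievable recovery.

`simulateMarkovSwitcher` emits template activity per hidden Markov state
(geometric dwells). The closed-loop validation conditions are dwell
probability 0.97 per state (mean dwell 33 frames, about 11 s at 3
frames/s, a realistic locomotor-state time scale), 4-channel templates,
observation noise SD 0.15, 6000 training frames, and $10^5$ simulated
steps.

These generators produce stationary, low-dimensional dynamics with known
phase, loop identity, and dwell laws. They do not emulate bleaching,
non-stationarity across a session, indicator kinetics, annotation
imprecision near behavioral transitions, or inter-individual differences
in neuronal activation — so passing recovery tests demonstrates
correctness of the machinery, not robustness to every artifact of real
recordings.

## Design choices that were genuinely open

- *Derivative before or after z-scoring*: the derivative is taken of the
  z-scored signal, matching the stated order of the preprocessing chain;
  a forward-difference option is provided.
- *"5 delays"* is read as lags $k = 0..5$ (six slices), the only reading
  consistent with 15 neurons embedding into 180 dimensions.
- *Neighborhood counting*: the successor counts toward `kNeighbors`, so
  `kNeighbors = 1` is exactly the deterministic limit.
- *Per-flux phase* (rather than one global phase) is the default: the
  $(\theta, \alpha)$ pairing implies each loop carries its own coherent
  phase. A global mode is available via `cluster = FALSE`.
- *Model archive format*: a single JSON file at full double precision
  (deterministic, text-based, readable from any language) rather than a
  binary container.
- *Forecast labels*: transition-time forecasts use modal per-bin behavior,
  as sampling would inject label noise into switch detection.
- Flux labels are 1-based contiguous integers, following R convention.

## Problem sizes used in the validation suite

The shipped tests run the full pipeline at deliberately desk-sized scales:
loops of 800–5000 frames, switcher recordings of 1000–6000 frames,
simulated paths of $10^5$ steps, 300–1000 ANOVA null replicates. These
sizes make every property computable from scratch in a test run while
keeping estimator noise (for example the sampling error of a mean dwell)
within the asserted tolerances.

## Known limitations

- Clustering cost is $O(n^2 \log n)$ in the number of states (FFT
  cross-correlations over all row pairs); recordings beyond a few thousand
  frames should be clustered on a subsample or fit per recording.
- The flow-based cluster merge assumes loop-to-loop hopping is rare; two
  loops exchanging mass faster than `mergeRate` per frame are reported as
  one flux.
- Phase is undefined for states whose eigenvector component is numerically
  zero (flagged NA and excluded from binning).
- The bin-level chain is first-order Markov; longer-memory structure in
  the data appears only through the embedding, not the simulation.

## A worked example

```{r example, eval = FALSE}
sim <- simulateNoisyLoops(nLoops = 1, omega = 2 * pi / 100, noiseSd = 0.1,
                          nFrames = 1000, nNeurons = 6, seed = 2)
pre <- preprocessRecording(sim$recording)
emb <- delayEmbed(pre$activity, pre$deriv, EmbedConfig(tau = 25, nDelays = 5))
M <- buildTransitionMatrix(emb)
mode <- leadingCyclicMode(M)
theta <- assignPhase(mode$vector)
# theta tracks the generator's latent angle up to rotation
```
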