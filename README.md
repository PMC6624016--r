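# fluxmap

Asymmetric diffusion map modeling of cyclic neural dynamics in R.

## The problem

Multineuronal recordings — for example whole-brain calcium imaging of
*C. elegans* at ~3 frames/s — are high-dimensional, noisy, and nonlinear,
yet the behaviorally relevant dynamics often live on a handful of loops in
phase space: the state circulates around stereotyped trajectories
(forward locomotion, backing, turns) and the interesting questions are
*which loop the system is on* and *where along it*. fluxmap extracts those
loops directly from data and turns them into a generative, two-variable
model that can simulate new activity, decode behavioral state, and
forecast when the next behavioral transition will happen.

## The method

Write the observed activity (plus its time derivative) at frame $t$,
delay-embedded over lags $0, \tau, \ldots, 5\tau$, as the state
$D_t$. An asymmetric diffusion kernel centered on the *next* observed
point casts local distances into a row-stochastic transition matrix

$$k_{FP}(D_t, D_j) = \exp\!\left(-\frac{\lVert D_{t+1} - D_j\rVert^2}{2\sigma^2}\right),
\qquad
\sigma^2 = \sigma_l(D_{t+1})\,\sigma_l(D_t)\,\langle k_{FP}\rangle ,$$

where $\sigma_l$ is the local trajectory SD in a 12-frame window and the
neighborhood is the successor plus its 11 nearest neighbors. Because the
kernel looks forward in time, $M$ is asymmetric and its spectrum is
complex: the largest-modulus complex eigenvalue defines the dominant
cyclic flux, and the componentwise argument of its eigenvector assigns
every state a phase $\theta$. Distinct loops $\alpha$ are identified by
Louvain maximum-modularity clustering of time-lagged row correlations of
the densified matrix $M^N$. States binned by $(\theta, \alpha)$ —
Gaussian bins, $\Delta\theta = 0.05$ rad — carry mean activity,
behavior distributions, and an empirical bin-level Markov chain that is
simulated to make predictions.

## A worked example

Recover the phase of a noisy limit cycle from 6 mixed observation
channels:

```r
library(fluxmap)

sim <- simulateNoisyLoops(nLoops = 1, omega = 2 * pi / 100, radius = 1,
                          noiseSd = 0.1, nFrames = 1000, nNeurons = 6,
                          seed = 2)
pre  <- preprocessRecording(sim$recording)   # smooth, z-score, differentiate
emb  <- delayEmbed(pre$activity, pre$deriv, EmbedConfig(tau = 25, nDelays = 5))
M    <- buildTransitionMatrix(emb)           # asymmetric diffusion kernel
mode <- leadingCyclicMode(M)
mode$value
#> [1] 0.9962822+0.062034i
```

The leading cyclic eigenvalue has modulus 0.998 — a strong, slowly
decaying rotational mode (the generator advances 2π/100 ≈ 0.0628 rad per
frame; Arg λ = 0.0622 matches). Its eigenvector phases track the hidden
angle:

```r
theta <- assignPhase(mode$vector)
truth <- sim$truth$phase[frameIndex(emb)]
# circular correlation between recovered and true phase: 0.998
```

The full pipeline (`fitPipeline`) chains these stages, bins states into a
`ManifoldModel`, and supports behavior decoding (`projectRecording`),
simulation (`runMarkov`, `pathToActivity`, `pathToBehavior`), dwell-time
statistics (`dwellStatistics`), and transition forecasting
(`timeToTransition` against the dwell-only null
`nullTimeToTransition`). `vignettes/fluxmap-methods.Rmd` documents the
model, parameters, and numerical choices; `inst/scripts/fluxmap.R` is a
command-line wrapper over the same functions.

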