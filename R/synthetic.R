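#' Parameters of the two-neuron stochastic relaxation oscillator
#'
#' The toy network couples a fast excitatory unit A and a slow inhibitory
#' unit B through logistic activation functions:
#' \deqn{dA/dt = -A + \sigma(w_{AA} A + w_{AB} B + b_A) + \epsilon}
#' \deqn{\tau_B\, dB/dt = -B + \sigma(w_{BA} A + w_{BB} B + b_B) + \epsilon'}
#' with \eqn{\sigma(x) = 1/(1+e^{-x})} and i.i.d. Gaussian noise added once
#' per integration step. With the default weights the deterministic system is
#' excitable and the noise drives recurrent relaxation-oscillation excursions.
#'
#' Note the noise is applied per forward-Euler step without sqrt(dt) scaling,
#' so its effective magnitude depends on \code{dt}; \code{noiseSd} defaults to
#' 0.1 (interpreted as a standard deviation; set
#' \code{noiseAsVariance = TRUE} to read it as a variance).
#'
#' @param wAA,wAB,bA weights and bias of the A unit.
#' @param wBA,wBB,bB weights and bias of the B unit.
#' @param tauB timescale multiplier of the B unit (> 0).
#' @param noiseSd per-step noise standard deviation (>= 0).
#' @param noiseAsVariance if \code{TRUE}, \code{noiseSd} is interpreted as a
#'   variance and its square root used.
#' @param dt forward-Euler integration step (> 0).
#' @return a named list of validated parameters.
#' @examples
#' p <- twoNeuronParams(noiseSd = 0)
#' @export
twoNeuronParams <- function(wAA = 8, wAB = -6, bA = -0.34,
                            wBA = 16, wBB = -2, bB = -2.5,
                            tauB = 6, noiseSd = 0.1,
                            noiseAsVariance = FALSE, dt = 0.01) {
  stopifnot(noiseSd >= 0, dt > 0, tauB > 0)
  if (noiseAsVariance) noiseSd <- sqrt(noiseSd)
  list(wAA = wAA, wAB = wAB, bA = bA, wBA = wBA, wBB = wBB, bB = bB,
       tauB = tauB, noiseSd = noiseSd, dt = dt)
}

#' Logistic activation
#' @param x numeric.
#' @return \code{1/(1+exp(-x))}.
#' @export
logisticSigma <- function(x) 1 / (1 + exp(-x))

#' Simulate the two-neuron relaxation oscillator
#'
#' Forward-Euler integration of the two-unit excitable network (see
#' \code{\link{twoNeuronParams}}), with fresh Gaussian noise draws for each
#' unit at every step. Output is bit-identical for identical seeds.
#'
#' @param params list from \code{\link{twoNeuronParams}}.
#' @param nSteps number of retained steps (>= 1).
#' @param init length-2 numeric initial state (A, B); default c(0.5, 0.5).
#' @param seed integer RNG seed.
#' @param burnIn steps discarded before recording (default 1000).
#' @param frameRate nominal frames/s attached to the output recording.
#' @return list with \code{recording} (a \linkS4class{Recording} with neurons
#'   "A" and "B") and \code{truth} (list with the parameters and initial
#'   state).
#' @examples
#' sim <- simulateTwoNeuron(twoNeuronParams(), nSteps = 500, seed = 1)
#' sim$recording
#' @export
simulateTwoNeuron <- function(params = twoNeuronParams(), nSteps,
                              init = c(0.5, 0.5), seed = 1L,
                              burnIn = 1000L, frameRate = 3) {
  stopifnot(nSteps >= 1, length(init) == 2)
  set.seed(seed)
  p <- params
  total <- burnIn + nSteps
  out <- matrix(NA_real_, total, 2)
  a <- init[1]; b <- init[2]
  for (t in seq_len(total)) {
    eps <- if (p$noiseSd > 0) rnorm(2, 0, p$noiseSd) else c(0, 0)
    a1 <- a + p$dt * (-a + logisticSigma(p$wAA * a + p$wAB * b + p$bA)) + eps[1]
    b1 <- b + (p$dt / p$tauB) *
      (-b + logisticSigma(p$wBA * a + p$wBB * b + p$bB)) + eps[2]
    if (!is.finite(a1) || !is.finite(b1))
      stop("two-neuron simulation diverged to a non-finite state at step ", t)
    a <- a1; b <- b1
    out[t, ] <- c(a, b)
  }
  out <- out[(burnIn + 1):total, , drop = FALSE]
  rec <- Recording(out, neuronNames = c("A", "B"), frameRate = frameRate,
                   animalId = paste0("twoNeuron_seed", seed))
  list(recording = rec, truth = list(params = p, init = init, seed = seed))
}

#' Locate a deterministic fixed point of the two-neuron system
#'
#' Solves \eqn{A = \sigma(w_{AA}A + w_{AB}B + b_A)},
#' \eqn{B = \sigma(w_{BA}A + w_{BB}B + b_B)} by damped fixed-point iteration
#' followed by a Newton polish.
#'
#' @param params list from \code{\link{twoNeuronParams}}.
#' @param start starting guess, length 2.
#' @param tol convergence tolerance on the residual.
#' @return length-2 numeric fixed point.
#' @export
twoNeuronFixedPoint <- function(params = twoNeuronParams(), start = c(0.2, 0.2),
                                tol = 1e-12) {
  p <- params
  g <- function(x) c(logisticSigma(p$wAA * x[1] + p$wAB * x[2] + p$bA),
                     logisticSigma(p$wBA * x[1] + p$wBB * x[2] + p$bB))
  x <- start
  for (i in 1:5000) {
    xn <- 0.5 * x + 0.5 * g(x)
    if (max(abs(xn - x)) < tol) break
    x <- xn
  }
  # Newton polish on F(x) = g(x) - x
  for (i in 1:50) {
    fx <- g(x) - x
    if (max(abs(fx)) < tol) break
    h <- 1e-7
    J <- cbind((g(x + c(h, 0)) - g(x)) / h, (g(x + c(0, h)) - g(x)) / h) -
      diag(2)
    x <- x - solve(J, fx)
  }
  x
}

#' Simulate noisy multi-loop limit-cycle trajectories
#'
#' Generates a latent 2-D point rotating at angular speed \code{omega} around
#' one of \code{nLoops} disjoint circle centers, with Gaussian noise on the
#' latent coordinates, then mixes the latent plane linearly into
#' \code{nNeurons} observation channels. When \code{nLoops > 1} the
#' trajectory hops stochastically to another loop whenever it passes through
#' a designated junction phase. Ground-truth phase (the latent angle) and
#' loop identity are returned per frame.
#'
#' @param nLoops number of loops (>= 1).
#' @param omega angular speed, radians/frame; recycled across loops.
#' @param radius loop radius (latent units).
#' @param noiseSd SD of latent additive Gaussian noise per frame.
#' @param nFrames number of frames.
#' @param nNeurons number of observation channels (>= 2).
#' @param seed integer RNG seed.
#' @param hopProb probability of switching loop at each junction passage
#'   (default 0.2: hops are occasional, so the system completes several
#'   revolutions per loop visit).
#' @param centerSpacing distance between adjacent loop centers; default
#'   \code{4 * radius} (well-separated).
#' @param frameRate nominal frames/s of the output recording.
#' @return list with \code{recording} (a \linkS4class{Recording}) and
#'   \code{truth} (list with per-frame \code{phase} in \eqn{(-\pi,\pi]},
#'   integer \code{loopId}, the latent coordinates and the mixing matrix).
#' @examples
#' sim <- simulateNoisyLoops(nLoops = 1, omega = 2 * pi / 100, nFrames = 300,
#'                           nNeurons = 4, seed = 2)
#' head(sim$truth$phase)
#' @export
simulateNoisyLoops <- function(nLoops = 1, omega = 2 * pi / 100, radius = 1,
                               noiseSd = 0.05, nFrames = 1000, nNeurons = 4,
                               seed = 1L, hopProb = 0.2,
                               centerSpacing = 4 * radius, frameRate = 3) {
  stopifnot(nLoops >= 1, nFrames >= 1)
  if (nNeurons < 2) stop("nNeurons must be >= 2 (mixing needs >= 2 channels)")
  set.seed(seed)
  omega <- rep_len(omega, nLoops)
  centers <- cbind((seq_len(nLoops) - 1) * centerSpacing, 0)
  junction <- pi  # hops permitted when crossing the junction phase
  phase <- numeric(nFrames); loop <- integer(nFrames)
  latent <- matrix(0, nFrames, 2)
  ph <- -pi + stats::runif(1) * 2 * pi
  lp <- 1L
  for (t in seq_len(nFrames)) {
    prev <- ph
    ph <- ph + omega[lp]
    # wrap to (-pi, pi]
    wrapped <- ph > pi
    if (wrapped) ph <- ph - 2 * pi
    if (nLoops > 1 && wrapped && stats::runif(1) < hopProb) {
      # crossing the junction (theta = pi): hop to a uniformly chosen other loop
      others <- setdiff(seq_len(nLoops), lp)
      lp <- others[sample.int(length(others), 1L)]
    }
    phase[t] <- ph; loop[t] <- lp
    latent[t, ] <- centers[lp, ] + radius * c(cos(ph), sin(ph))
  }
  if (noiseSd > 0)
    latent <- latent + matrix(rnorm(2 * nFrames, 0, noiseSd), nFrames, 2)
  mix <- matrix(rnorm(2 * nNeurons), 2, nNeurons)
  traces <- latent %*% mix
  rec <- Recording(traces,
                   neuronNames = paste0("ch", seq_len(nNeurons)),
                   frameRate = frameRate,
                   animalId = paste0("loops_seed", seed))
  list(recording = rec,
       truth = list(phase = phase, loopId = loop, latent = latent,
                    mixing = mix, omega = omega, seed = seed))
}

#' Simulate a Markov behavior switcher with per-state activity templates
#'
#' A hidden state follows a discrete-time Markov chain whose state s repeats
#' itself with probability \code{dwellP[s]} and otherwise jumps uniformly to
#' another state; emitted activity is \code{templates[[s]]} plus Gaussian
#' noise. The true dwell-time distribution of state s is geometric with mean
#' \code{1 / (1 - dwellP[s])}.
#'
#' @param dwellP numeric vector of per-state self-transition probabilities,
#'   each strictly inside (0, 1).
#' @param templates list (one per state) of mean activity vectors, all the
#'   same length.
#' @param noiseSd SD of additive Gaussian observation noise.
#' @param nFrames number of frames.
#' @param seed integer RNG seed.
#' @param stateNames optional behavior label per state; defaults to
#'   \code{"state1"}, ... (use e.g. c("forward", "backward")).
#' @param frameRate nominal frames/s.
#' @return list with \code{recording} (a \linkS4class{Recording} carrying the
#'   true behavior labels) and \code{truth} (per-frame \code{state},
#'   \code{behavior}, and \code{dwellParams} with the geometric means).
#' @examples
#' sim <- simulateMarkovSwitcher(c(0.9, 0.8),
#'   templates = list(c(1, 0), c(0, 1)), noiseSd = 0.1,
#'   nFrames = 500, seed = 3)
#' table(sim$truth$behavior)
#' @export
simulateMarkovSwitcher <- function(dwellP, templates, noiseSd = 0.1,
                                   nFrames = 1000, seed = 1L,
                                   stateNames = NULL, frameRate = 3) {
  nS <- length(dwellP)
  stopifnot(nS >= 2, nFrames >= 1)
  if (any(dwellP <= 0 | dwellP >= 1))
    stop("every dwellP must lie strictly inside (0, 1)")
  if (length(templates) != nS)
    stop("need one template per state")
  dims <- lengths(templates)
  if (length(unique(dims)) != 1)
    stop("templates have mismatched dimensionality: ",
         paste(dims, collapse = ", "))
  if (is.null(stateNames)) stateNames <- paste0("state", seq_len(nS))
  set.seed(seed)
  state <- integer(nFrames)
  s <- sample.int(nS, 1L)
  for (t in seq_len(nFrames)) {
    state[t] <- s
    if (stats::runif(1) >= dwellP[s])
      s <- if (nS == 2) 3L - s else sample(setdiff(seq_len(nS), s), 1L)
  }
  tmpl <- do.call(rbind, templates)
  act <- tmpl[state, , drop = FALSE]
  if (noiseSd > 0)
    act <- act + matrix(rnorm(length(act), 0, noiseSd), nrow(act), ncol(act))
  behavior <- stateNames[state]
  rec <- Recording(act, neuronNames = paste0("n", seq_len(ncol(act))),
                   frameRate = frameRate, behavior = behavior,
                   animalId = paste0("switcher_seed", seed))
  list(recording = rec,
       truth = list(state = state, behavior = behavior,
                    dwellParams = list(dwellP = dwellP,
                                       meanDwell = 1 / (1 - dwellP)),
                    templates = tmpl, seed = seed))
}
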