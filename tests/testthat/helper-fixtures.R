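# shared fixture builders and independent metrics used across test files

# circular (Fisher-Lee) correlation between two angle vectors
circCor <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  aa <- a - atan2(mean(sin(a)), mean(cos(a)))
  bb <- b - atan2(mean(sin(b)), mean(cos(b)))
  sum(sin(aa) * sin(bb)) / sqrt(sum(sin(aa)^2) * sum(sin(bb)^2))
}

# adjusted Rand index, computed from first principles
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  expected <- sc(rowSums(tab)) * sc(colSums(tab)) / choose(n, 2)
  (sc(tab) - expected) /
    ((sc(rowSums(tab)) + sc(colSums(tab))) / 2 - expected)
}

# single noisy loop taken through preprocessing and embedding
loopEmbedding <- function(nFrames = 1000, noiseSd = 0.1, seed = 2,
                          tau = 25, nDelays = 5, nNeurons = 6,
                          nLoops = 1, ...) {
  sim <- simulateNoisyLoops(nLoops = nLoops, omega = 2 * pi / 100,
                            radius = 1, noiseSd = noiseSd,
                            nFrames = nFrames, nNeurons = nNeurons,
                            seed = seed, ...)
  pre <- preprocessRecording(sim$recording)
  emb <- delayEmbed(pre$activity, pre$deriv,
                    EmbedConfig(tau = tau, nDelays = nDelays))
  list(sim = sim, emb = emb,
       truthPhase = sim$truth$phase[frameIndex(emb)],
       truthLoop = sim$truth$loopId[frameIndex(emb)])
}

# standard two-state switcher recording with behavior labels
switcherRecording <- function(nFrames = 3000, seed = 11, dwellP = 0.97,
                              noiseSd = 0.15,
                              templates = list(c(1, 0, 0.5, 0.2),
                                               c(0, 1, 0.1, 0.8))) {
  simulateMarkovSwitcher(rep(dwellP, 2), templates = templates,
                         noiseSd = noiseSd, nFrames = nFrames, seed = seed,
                         stateNames = c("forward", "backward"))
}
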