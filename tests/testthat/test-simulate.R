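# minimal hand-built manifold with a deterministic bin cycle
cycleModel <- function(n = 10, behaviors = NULL) {
  bins <- data.frame(alpha = 1L, thetaCenter = seq(-pi + 0.1, pi, length.out = n),
                     thetaSd = 0.3, occupancy = rep(10L, n),
                     unassigned = FALSE,
                     modalBehavior = behaviors %||% rep("forward", n))
  P <- Matrix::sparseMatrix(i = 1:n, j = c(2:n, 1), x = 1, dims = c(n, n))
  lev <- unique(bins$modalBehavior)
  bp <- matrix(0, n, length(lev), dimnames = list(NULL, lev))
  bp[cbind(1:n, match(bins$modalBehavior, lev))] <- 1
  new("ManifoldModel", bins = bins,
      meanEmbedded = matrix(seq_len(n), n, 4),
      meanActivity = matrix(seq_len(n), n, 2,
                            dimnames = list(NULL, c("a", "b"))),
      behaviorProb = bp, behaviorLevels = lev, binTrans = P,
      modelNeurons = c("a", "b"), allNeurons = c("a", "b"),
      config = EmbedConfig(1, 0), preprocess = list(sigmaFrames = 1),
      assignments = rep(1:n, each = 10L),
      trainActivity = matrix(0, 10 * n, 2,
                             dimnames = list(NULL, c("a", "b"))),
      trainRecordingId = rep(1L, 10 * n), seed = 1L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a permutation bin matrix simulates an exact deterministic cycle", {
  m <- cycleModel(6)
  path <- runMarkov(m, 1, 12, seed = 1)
  expect_equal(path, rep(c(1:6), 3)[1:13], ignore_attr = TRUE)
  expect_identical(runMarkov(m, 1, 50, seed = 9),
                   runMarkov(m, 1, 50, seed = 9))
})

test_that("two-bin chain reproduces its switch probability", {
  m <- cycleModel(2)
  p <- 0.3
  m@binTrans <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                                     x = c(1 - p, p, p, 1 - p), dims = c(2, 2))
  path <- runMarkov(m, 1, 1e5, seed = 3)
  switches <- mean(path[-1] != path[-length(path)])
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(switches - p), 3 * se)
})

test_that("paths map to activity deterministically in mean mode and seeded in sample mode", {
  m <- cycleModel(5)
  path <- rep(3L, 10)
  act <- pathToActivity(path, m)
  expect_true(all(act[, 1] == 3))
  expect_identical(pathToActivity(path, m), act)
  s1 <- pathToActivity(path, m, mode = "sample", seed = 4)
  s2 <- pathToActivity(path, m, mode = "sample", seed = 4)
  expect_identical(s1, s2)
})

test_that("behavior mapping honors pure bins, sampling frequencies, and modal determinism", {
  m <- cycleModel(4, behaviors = c("forward", "forward", "backward", "forward"))
  expect_equal(pathToBehavior(c(3L, 3L), m), c("backward", "backward"))
  m@behaviorProb[2, ] <- c(0.7, 0.3)
  freq <- table(pathToBehavior(rep(2L, 1e5), m, mode = "sample", seed = 5))
  se <- sqrt(0.7 * 0.3 / 1e5)
  expect_lt(abs(freq[["forward"]] / 1e5 - 0.7), 3 * se)
  expect_identical(pathToBehavior(1:4, m), pathToBehavior(1:4, m))
})

test_that("dwell statistics count runs and merge bouts by the gap rule", {
  s1 <- c(rep("forward", 50), rep("backward", 20), rep("forward", 50))
  d1 <- dwellStatistics(s1, medianWindow = 1)
  expect_equal(d1$forward, c(50, 50))
  expect_equal(d1$backward, 20)
  expect_equal(d1$bouts, 20)
  # gap of 10 <= 30: one bout spanning 50 frames
  s2 <- c(rep("backward", 20), rep("forward", 10), rep("backward", 20))
  d2 <- dwellStatistics(s2, medianWindow = 1)
  expect_equal(d2$bouts, 50)
  # gap of 31 > 30: two separate bouts
  s3 <- c(rep("backward", 20), rep("forward", 31), rep("backward", 20))
  expect_equal(dwellStatistics(s3, medianWindow = 1)$bouts, c(20, 20))
  expect_error(dwellStatistics(character(0)), "empty")
})

test_that("the median filter removes short glitches inside long runs", {
  s <- c(rep("forward", 25), rep("backward", 3), rep("forward", 22))
  filt <- medianFilterLabels(s, 11)
  expect_equal(unique(filt), "forward")
  d <- dwellStatistics(s, medianWindow = 11)
  expect_equal(d$forward, 50)
  # brute-force mode filter oracle at a few positions
  for (i in c(2, 26, 40)) {
    lo <- max(1, i - 5); hi <- min(50, i + 5)
    tab <- table(s[lo:hi])
    expect_equal(filt[i], names(tab)[which.max(tab)])
  }
})

test_that("forecasts on a deterministic cycle are exact and seeded", {
  m <- cycleModel(10, behaviors = c(rep("backward", 6), "forward",
                                    rep("backward", 3)))
  fc <- timeToTransition(m, startBin = 2, targetBehavior = "forward",
                         nSims = 20, seed = 2)
  expect_equal(fc$mean, 5)
  expect_equal(var(fc$times), 0)
  expect_equal(timeToTransition(m, 7, "forward", nSims = 5, seed = 1)$mean, 0)
  expect_error(timeToTransition(m, 2, "sleep", nSims = 5), "not the modal")
})

test_that("the dwell-time null is memoryless for exponential dwells and exact for constants", {
  set.seed(8)
  dw <- stats::rexp(1e5, rate = 0.1)
  for (t0 in c(0, 5, 20)) {
    res <- nullTimeToTransition(dw, t0)
    expect_lt(abs(res$mean - 10) / 10, 0.05)
  }
  expect_equal(nullTimeToTransition(10, 4)$mean, 6)
  expect_equal(nullTimeToTransition(dw, 0)$mean, mean(dw))
  expect_false(nullTimeToTransition(c(1, 2), 5)$defined)
})

test_that("timeSinceOnset restarts at every behavior change", {
  lab <- c("a", "a", "b", "b", "b", "a")
  expect_equal(timeSinceOnset(lab), c(0L, 1L, 0L, 1L, 2L, 0L))
})

test_that("kernel-smoothed dwell r2 is high for same-law samples", {
  set.seed(9)
  a <- rgeom(2000, 0.05) + 1
  b <- rgeom(2000, 0.05) + 1
  c <- rgeom(2000, 0.3) + 1
  expect_gt(dwellR2(a, b), 0.9)
  expect_lt(dwellR2(a, c), dwellR2(a, b))
})
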