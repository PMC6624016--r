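test_that("phase warping normalizes duration and centers instances", {
  # same shape at two durations warps to the same 100-vector
  shape <- function(n) sin(seq(0, 2 * pi, length.out = n))
  w1 <- phaseWarp(shape(60), 1, 60)
  w2 <- phaseWarp(shape(200), 1, 200)
  expect_equal(length(w1), 100)
  expect_lt(max(abs(w1 - w2)), 0.01)
  expect_lt(abs(mean(w1)), 1e-9)
  # a linear ramp becomes antisymmetric around mid-phase
  wr <- phaseWarp(seq(0, 1, length.out = 50), 1, 50)
  expect_lt(abs(wr[50] + wr[51]), 0.03)
  expect_equal(phaseWarp(rep(2, 30), 1, 30), rep(0, 100))
  expect_error(phaseWarp(1:10, 5, 5), "exceed")
})

test_that("consistency test is calibrated under the null and powered under shift", {
  set.seed(10)
  nullP <- replicate(300, {
    w <- matrix(rnorm(20 * 100), 20, 100)
    consistencyTest(w, rep(1:4, each = 5))$p.value
  })
  frac <- mean(nullP < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
  # one animal shifted 3 SD along the dominant direction -> tiny p
  set.seed(11)
  base <- matrix(rnorm(20 * 100), 20, 100)
  dir <- rep(1, 100) / 10
  base[16:20, ] <- base[16:20, ] + 3 * 10 * matrix(dir, 5, 100, byrow = TRUE)
  expect_lt(consistencyTest(base, rep(1:4, each = 5))$p.value, 0.001)
  # identical instances everywhere: degenerate, flagged
  same <- matrix(rep(sin(1:100 / 5), 8), 8, 100, byrow = TRUE)
  res <- consistencyTest(same, rep(1:2, each = 4))
  expect_true(res$degenerate)
  expect_error(consistencyTest(base, rep(1, 20)), "2 animals")
})

test_that("threshold optimizer equals the exhaustive scan and handles separation", {
  sep <- optimizeThreshold(c(5, 6, 7), c(1, 2, 3))
  expect_equal(sep$probability, 1)
  expect_gt(sep$threshold, 3)
  set.seed(12)
  same <- optimizeThreshold(rnorm(500), rnorm(500))
  expect_lte(same$probability, 0.6)
  for (i in 1:20) {
    st <- rnorm(sample(3:40, 1), mean = runif(1, 0, 2))
    sf <- rnorm(sample(3:40, 1))
    got <- optimizeThreshold(st, sf)
    cand <- sort(unique(c(st, sf)))
    pAll <- vapply(cand, function(x)
      sum(st >= x) / (length(st) + sum(sf >= x)), numeric(1))
    expect_equal(got$probability, max(pAll))
    expect_equal(got$threshold, cand[which.max(pAll)])
  }
})

test_that("template decoding succeeds on clean repeats and collapses under shuffling", {
  set.seed(13)
  n <- 1200
  motif <- matrix(rnorm(10 * 3, sd = 2), 10, 3)
  act <- matrix(rnorm(n * 3, sd = 0.3), n, 3)
  onsets <- seq(60, n - 60, by = 80)
  for (o in onsets) act[(o - 9):o, ] <- act[(o - 9):o, ] + motif
  half <- seq_along(onsets) %% 2 == 0
  res <- templateDecode(act, onsets[half], act, onsets[!half],
                        ignoreOnsets = onsets[half])
  expect_gt(res$probability, 0.8)
  # random "events" as training: probability collapses toward chance
  set.seed(14)
  fake <- sort(sample(20:(n - 20), sum(half)))
  shuf <- templateDecode(act, fake, act, onsets[!half],
                         ignoreOnsets = fake)
  expect_lt(shuf$probability, res$probability / 2)
})

test_that("decoding onsets of switcher backing events beats chance within-animal", {
  sim <- switcherRecording(nFrames = 6000, seed = 15, dwellP = 0.98,
                           noiseSd = 0.3)
  beh <- behaviorLabels(sim$recording)
  onsets <- which(beh[-1] == "backward" & beh[-length(beh)] == "forward") + 1
  # the switcher's onset signature is the step itself, so place the labeled
  # event mid-window (well inside the 10-frame matching tolerance)
  onsets <- onsets[onsets > 10 & onsets < nFrames(sim$recording) - 10] + 5
  p <- bootstrapDecode(activity(sim$recording), onsets, nBoot = 20, seed = 1)
  expect_gt(median(p, na.rm = TRUE), 0.3)
  # shuffled "events" collapse toward chance
  set.seed(2)
  fake <- sort(sample(30:5970, length(onsets)))
  pf <- bootstrapDecode(activity(sim$recording), fake, nBoot = 10, seed = 1)
  expect_lt(median(pf, na.rm = TRUE), median(p, na.rm = TRUE))
})

test_that("KL divergence obeys identity, nonnegativity, and the worked example", {
  expect_equal(klDivergence(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-9)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)), log(5 / 3),
               tolerance = 1e-6)
  set.seed(16)
  for (i in 1:20) {
    p <- runif(6); q <- runif(6)
    expect_gte(klDivergence(p / sum(p), q / sum(q)), -1e-12)
  }
})

test_that("min-binned KL vanishes for identical samples and flags degenerate input", {
  set.seed(17)
  x <- rgeom(2000, 0.05) + 1
  expect_lt(minBinnedKL(x, x), 1e-10)
  y <- rgeom(2000, 0.05) + 1
  z <- rgeom(2000, 0.5) + 1
  expect_lt(minBinnedKL(x, y), minBinnedKL(x, z))
  expect_error(minBinnedKL(rep(1, 5), x), "degenerate")
})

test_that("relative information is near 1 for same-generator simulations", {
  set.seed(18)
  gen <- function(seed) {
    sim <- simulateMarkovSwitcher(c(0.97, 0.97), list(c(1, 0), c(0, 1)),
                                  noiseSd = 0, nFrames = 1e5, seed = seed)
    dwellStatistics(sim$truth$behavior, medianWindow = 1,
                    forwardLabel = "state1", backwardLabel = "state2")
  }
  o <- gen(1); r <- gen(2); m <- gen(3)
  keep <- c("forward", "backward", "bouts")
  res <- relativeInformation(o[keep], r[keep], m[keep])
  expect_gt(res$iRel, 0.9)
  expect_lt(res$iRel, 1.1)
  expect_gte(res$iTotReference, 0)
})
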