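test_that("bin layout follows the ceiling(2*pi/delta) rule per flux", {
  b1 <- makeBins(rep(1L, 10), deltaTheta = 0.05)
  expect_equal(nrow(b1), 126)
  b2 <- makeBins(rep(1:2, 5), deltaTheta = 0.05)
  expect_equal(nrow(b2), 252)
  b3 <- makeBins(rep(1L, 4), deltaTheta = pi)
  expect_equal(nrow(b3), 2)
  expect_true(all(b1$thetaCenter > -pi & b1$thetaCenter <= pi))
})

test_that("bin assignment is nearest-center, circular, and tie-broken low", {
  bins <- makeBins(rep(1L, 3), deltaTheta = 0.05)
  # exact centers map to themselves
  idx <- assignBin(bins$thetaCenter[c(1, 50, 126)], 1L, bins)
  expect_equal(idx, c(1L, 50L, 126L))
  # midway between adjacent centers: lower index wins
  mid <- (bins$thetaCenter[10] + bins$thetaCenter[11]) / 2
  expect_equal(assignBin(mid, 1L, bins), 10L)
  # wrap-around: brute-force circular scan agrees near +/- pi
  brute <- function(th) {
    d <- abs(th - bins$thetaCenter)
    which.min(pmin(d, 2 * pi - d))
  }
  for (th in c(-pi + 0.01, pi - 0.01, pi, -3.1, 3.1))
    expect_equal(assignBin(th, 1L, bins), brute(th))
  expect_error(assignBin(0.1, 99L, bins), "no bins")
})

test_that("bin summaries are the arithmetic means of their members", {
  l <- loopEmbedding(nFrames = 500, seed = 4, tau = 5, nDelays = 2)
  M <- buildTransitionMatrix(l$emb)
  fd <- fluxDecompose(M, cluster = FALSE)
  beh <- ifelse(l$truthPhase > 0, "forward", "backward")
  model <- buildManifold(l$emb, fd, behaviors = beh, deltaTheta = 0.2)
  bins <- binInfo(model)
  assign <- model@assignments
  full <- which(bins$occupancy >= 5)[1:3]
  for (b in full) {
    members <- which(assign == b)
    expect_equal(model@meanEmbedded[b, ],
                 unname(colMeans(embeddedPoints(l$emb)[members, , drop = FALSE])),
                 tolerance = 1e-12)
    expect_equal(sum(behaviorDist(model)[b, ]), 1, tolerance = 1e-12)
  }
  # a bin whose members share one behavior is pure
  pure <- which(bins$occupancy > 0 &
                  apply(behaviorDist(model), 1, max) == 1)
  expect_gt(length(pure), 0)
  # empty bins are flagged with no summaries
  empty <- which(bins$occupancy == 0)
  if (length(empty)) {
    expect_true(all(bins$unassigned[empty]))
    expect_true(all(model@meanEmbedded[empty, ] == 0))
  }
  expect_equal(sum(bins$occupancy), sum(!is.na(assign)))
})

test_that("bin transition matrix reproduces empirical switch fractions", {
  # deterministic cycle of bins
  cyc <- rep(1:3, 20)
  P <- binTransitionCounts(cyc, nBins = 3)
  expect_equal(as.matrix(P),
               matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3), ignore_attr = TRUE)
  # two-state sequence: off-diagonal equals the observed switch fraction
  set.seed(2)
  s <- 1 + (cumsum(rbinom(2000, 1, 0.2)) %% 2)
  P2 <- as.matrix(binTransitionCounts(s, nBins = 2))
  emp <- sum(s[-1] != s[-2000] & s[-2000] == 1) / sum(s[-2000] == 1)
  expect_equal(P2[1, 2], emp, tolerance = 1e-12)
  expect_true(all(abs(rowSums(P2) - 1) < 1e-9))
})

test_that("self-projection reassigns training frames to their own bins", {
  # noiseless loop: embedded points sit exactly on the manifold, so the
  # nearest bin centroid is (almost always) the bin the frame defined
  sim <- simulateNoisyLoops(nLoops = 1, omega = 2 * pi / 100, noiseSd = 0,
                            nFrames = 1200, nNeurons = 5, seed = 21)
  model <- fitPipeline(list(sim$recording), tau = 10, nDelays = 2,
                       cluster = FALSE, deltaTheta = 0.1, seed = 1)
  proj <- projectRecording(model, sim$recording)
  assign <- model@assignments
  ok <- !is.na(assign)
  agree <- mean(proj$bin[ok] == assign[ok], na.rm = TRUE)
  expect_gte(agree, 0.95)
  expect_error(projectRecording(model, sim$recording,
                                availableNeurons = character(0)),
               "no shared neurons")
})

test_that("masking duplicated channels does not change projections", {
  sim <- simulateMarkovSwitcher(c(0.9, 0.9), list(c(1, 0), c(0, 1)),
                                noiseSd = 0.1, nFrames = 600, seed = 3,
                                stateNames = c("forward", "backward"))
  base <- activity(sim$recording)
  # every channel duplicated: the masked metric is an exact scalar multiple
  rec <- Recording(cbind(base, base),
                   neuronNames = c("n1", "n2", "n1b", "n2b"),
                   behavior = behaviorLabels(sim$recording))
  model <- fitPipeline(list(rec), tau = 3, nDelays = 1, cluster = FALSE,
                       deltaTheta = 0.2, seed = 1)
  full <- projectRecording(model, rec)
  masked <- projectRecording(model, rec, availableNeurons = c("n1", "n2"))
  expect_identical(full$bin, masked$bin)
})

test_that("modal bin behavior decodes held-out frames above the base rate", {
  train <- switcherRecording(nFrames = 3000, seed = 31)
  test <- switcherRecording(nFrames = 1000, seed = 32)
  model <- fitPipeline(list(train$recording), tau = 5, nDelays = 2,
                       cluster = FALSE, deltaTheta = 0.1, seed = 1)
  proj <- projectRecording(model, test$recording)
  truth <- behaviorLabels(test$recording)[proj$frameIndex]
  usable <- proj$behavior != "unassigned"
  acc <- mean(proj$behavior[usable] == truth[usable])
  base <- max(table(truth)) / length(truth)
  bt <- binom.test(sum(proj$behavior[usable] == truth[usable]), sum(usable),
                   p = base, alternative = "greater")
  expect_lt(bt$p.value, 0.01)
  expect_gt(acc, base)
})

test_that("leave-one-animal-out decoding stays near within-sample accuracy", {
  sims <- lapply(41:45, function(s) switcherRecording(nFrames = 800, seed = s))
  recs <- lapply(sims, `[[`, "recording")
  model4 <- fitPipeline(recs[1:4], tau = 5, nDelays = 2, cluster = FALSE,
                        deltaTheta = 0.1, seed = 1)
  acc <- function(model, rec) {
    proj <- projectRecording(model, rec)
    truth <- behaviorLabels(rec)[proj$frameIndex]
    usable <- proj$behavior != "unassigned"
    mean(proj$behavior[usable] == truth[usable])
  }
  within <- mean(vapply(recs[1:4], function(r) acc(model4, r), numeric(1)))
  heldOut <- acc(model4, recs[[5]])
  expect_gt(within, 0.7)
  expect_lt(abs(within - heldOut), 0.05)
})

test_that("dpca coordinates flatten a planar loop and count bins", {
  l <- loopEmbedding(nFrames = 800, noiseSd = 0.03, seed = 6, tau = 5,
                     nDelays = 2)
  M <- buildTransitionMatrix(l$emb)
  fd <- fluxDecompose(M, cluster = FALSE)
  model <- buildManifold(l$emb, fd, deltaTheta = 0.1)
  coords <- dpcaCoordinates(model)
  expect_equal(nrow(coords), sum(binInfo(model)$occupancy > 0))
  v <- apply(coords[, c("PC1", "PC2", "PC3")], 2, var)
  expect_lt(v[3] / (v[1] + v[2]), 0.05)
})
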