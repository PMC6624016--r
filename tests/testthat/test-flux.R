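# cyclic permutation matrix over n states: exact Fourier eigenstructure
cycleMatrix <- function(n) {
  M <- Matrix::sparseMatrix(i = 1:n, j = c(2:n, 1), x = 1, dims = c(n, n))
  new("TransitionMatrix", probs = M, frameIndex = 1:n,
      recordingId = rep(1L, n), terminal = integer(0))
}

test_that("leading cyclic mode of a 4-cycle is the imaginary unit", {
  mode <- leadingCyclicMode(cycleMatrix(4))
  expect_equal(mode$value, 0 + 1i, tolerance = 1e-10)
  expect_equal(Mod(mode$value), 1, tolerance = 1e-10)
})

test_that("a symmetric chain has no cyclic mode", {
  P <- Matrix::Matrix(matrix(0.5, 2, 2), sparse = TRUE)
  M <- new("TransitionMatrix", probs = P, frameIndex = 1:2,
           recordingId = c(1L, 1L), terminal = integer(0))
  expect_error(leadingCyclicMode(M), "no cyclic mode")
})

test_that("noisy single-loop transition matrix has a strong cyclic eigenvalue", {
  l <- loopEmbedding(nFrames = 600, seed = 2, tau = 10, nDelays = 3)
  M <- buildTransitionMatrix(l$emb)
  mode <- leadingCyclicMode(M)
  expect_gt(Mod(mode$value), 0.9)
  expect_lte(Mod(mode$value), 1)
  # dense eigensolver agreement on the same small matrix
  ev <- eigen(as.matrix(transitionProbs(M)), only.values = TRUE)$values
  cx <- ev[abs(Im(ev)) > 1e-8]
  expect_equal(Mod(mode$value), max(Mod(cx)), tolerance = 1e-8)
})

test_that("phases of a cyclic permutation are equally spaced quarters", {
  mode <- leadingCyclicMode(cycleMatrix(4))
  th <- assignPhase(mode$vector)
  d <- diff(th)
  d <- atan2(sin(d), cos(d))
  expect_equal(abs(d), rep(pi / 2, 3), tolerance = 1e-9)
  # conjugating the eigenvector flips raw phases; orientation rule restores
  thConj <- assignPhase(Conj(mode$vector))
  dc <- diff(thConj); dc <- atan2(sin(dc), cos(dc))
  expect_equal(sign(median(dc)), sign(median(d)))
})

test_that("recovered phase tracks the ground-truth latent angle", {
  l <- loopEmbedding(nFrames = 1000, noiseSd = 0.1, seed = 2)
  M <- buildTransitionMatrix(l$emb)
  mode <- leadingCyclicMode(M)
  th <- assignPhase(mode$vector)
  expect_gt(circCor(th, l$truthPhase), 0.95)
  # monotone advance along the loop
  ok <- !is.na(th)
  d <- diff(th[ok]); d <- atan2(sin(d), cos(d))
  expect_gt(mean(d > 0), 0.95)
})

test_that("densify reaches the row-fill target and preserves the spectrum", {
  l <- loopEmbedding(nFrames = 300, seed = 8, tau = 5, nDelays = 2)
  M <- buildTransitionMatrix(l$emb)
  keep <- setdiff(seq_len(nrow(transitionProbs(M))), M@terminal)
  P <- transitionProbs(M)[keep, keep]
  P <- Matrix::Diagonal(x = 1 / Matrix::rowSums(P)) %*% P
  dn <- densify(P, minFrac = 0.25)
  n <- nrow(P)
  fills <- apply(as.matrix(dn$matrix) > 0, 1, sum)
  expect_gte(min(fills), ceiling(0.25 * n))
  expect_gte(dn$exponent, 1)
  # lambda -> lambda^N on the dominant part of the spectrum
  ev1 <- eigen(as.matrix(P), only.values = TRUE)$values
  evN <- eigen(as.matrix(dn$matrix), only.values = TRUE)$values
  expect_equal(sort(Mod(evN), decreasing = TRUE)[1:5],
               sort(Mod(ev1)^dn$exponent, decreasing = TRUE)[1:5],
               tolerance = 1e-6)
  # an already dense matrix needs N = 1
  dense <- Matrix::Matrix(matrix(1 / n, n, n), sparse = TRUE)
  expect_equal(densify(dense)$exponent, 1)
})

test_that("a permutation cycle can never densify and is capped with a warning", {
  P <- Matrix::sparseMatrix(i = 1:100, j = c(2:100, 1), x = 1,
                            dims = c(100, 100))
  expect_warning(dn <- densify(P, minFrac = 0.25, maxExponent = 30),
                 "capped")
  expect_equal(dn$exponent, 30)
})

test_that("lagged correlation matches a brute-force shift scan", {
  set.seed(5)
  Md <- matrix(abs(rnorm(12 * 12)), 12, 12)
  C <- laggedRowCorrelation(Md)
  bruteMax <- function(x, y) {
    n <- length(y)
    max(vapply(0:(n - 1), function(s)
      cor(x, y[((seq_len(n) + s - 1) %% n) + 1]), numeric(1)))
  }
  for (i in c(1, 4)) for (j in c(7, 12)) {
    expect_equal(C[i, j], max(bruteMax(Md[i, ], Md[j, ]),
                              bruteMax(Md[j, ], Md[i, ])),
                 tolerance = 1e-8)
  }
  expect_equal(diag(C), rep(1, 12))
  # a constant row yields correlation 0 against everything
  Md[3, ] <- 2
  C0 <- laggedRowCorrelation(Md)
  expect_true(all(C0[3, -3] == 0))
})

test_that("lagged correlation of circularly shifted rows is exactly 1", {
  set.seed(6)
  y <- rnorm(30)
  Md <- matrix(0, 30, 30)
  for (i in 1:30) Md[i, ] <- y[((seq_len(30) + i - 2) %% 30) + 1]
  C <- laggedRowCorrelation(Md)
  expect_true(all(abs(C - 1) < 1e-9))
  # block-diagonal orthogonal supports: cross-block below within-block
  A <- matrix(0, 20, 20)
  for (i in 1:10) A[i, ((i %% 10) + 1)] <- 1
  for (i in 11:20) A[i, 10 + (i %% 10) + 1] <- 1
  C2 <- laggedRowCorrelation(A)
  within <- c(C2[1:10, 1:10][upper.tri(matrix(0, 10, 10))],
              C2[11:20, 11:20][upper.tri(matrix(0, 10, 10))])
  cross <- C2[1:10, 11:20]
  expect_lt(max(cross), min(within) + 1e-9)
})

test_that("modularity clustering recovers block structure", {
  C <- matrix(0.05, 30, 30)
  C[1:10, 1:10] <- 0.9
  C[11:20, 11:20] <- 0.9
  C[21:30, 21:30] <- 0.9
  diag(C) <- 1
  lab <- clusterFluxes(C, seed = 1)
  expect_equal(length(unique(lab)), 3)
  expect_equal(adjustedRand(lab, rep(1:3, each = 10)), 1)
})

test_that("flux decomposition separates two loops and phases each coherently", {
  l <- loopEmbedding(nFrames = 800, noiseSd = 0.08, seed = 3, tau = 5,
                     nDelays = 2, nLoops = 2)
  M <- buildTransitionMatrix(l$emb)
  fd <- fluxDecompose(M, seed = 1)
  expect_gte(adjustedRand(fluxLabels(fd), l$truthLoop), 0.9)
  expect_true(all(fluxLabels(fd) >= 1))
  # per-flux phase agrees with truth inside the dominant flux
  a1 <- which(fluxLabels(fd) == 1 & !is.na(statePhase(fd)))
  expect_gt(abs(circCor(statePhase(fd)[a1], l$truthPhase[a1])), 0.8)
})

test_that("single-loop data collapse onto one dominant flux", {
  l <- loopEmbedding(nFrames = 500, noiseSd = 0.05, seed = 4, tau = 5,
                     nDelays = 2)
  M <- buildTransitionMatrix(l$emb)
  fd <- fluxDecompose(M, seed = 1)
  expect_gte(max(table(fluxLabels(fd))) / length(fluxLabels(fd)), 0.9)
})
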