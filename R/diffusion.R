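#' Exact k-nearest neighbors of embedded points
#'
#' Brute-force Euclidean k-nearest neighbors (self excluded), computed in
#' chunks so memory stays bounded. Ties are broken deterministically toward
#' the lower point index. Duplicate points (distance 0) are permitted.
#'
#' @param points an \linkS4class{EmbeddedSeries} or a numeric matrix
#'   (rows = points).
#' @param k number of neighbors (1 <= k < number of points).
#' @return list with integer matrix \code{index} (n x k, neighbor indices in
#'   increasing-distance order) and numeric matrix \code{dist}.
#' @examples
#' nn <- nearestNeighbors(matrix(rnorm(40), 20, 2), k = 3)
#' @export
nearestNeighbors <- function(points, k) {
  pts <- if (is(points, "EmbeddedSeries")) points@points else as.matrix(points)
  n <- nrow(pts)
  if (k < 1 || k >= n)
    stop("k must satisfy 1 <= k < number of points (", n, ")")
  sq <- rowSums(pts^2)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  chunk <- max(16L, min(n, floor(4e7 / n)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    block <- pts[s:e, , drop = FALSE]
    d2 <- sweep(-2 * tcrossprod(block, pts), 2, sq, "+") + sq[s:e]
    d2[d2 < 0] <- 0
    for (r in seq_len(e - s + 1L)) {
      i <- s + r - 1L
      di <- d2[r, ]
      di[i] <- Inf                      # exclude self
      ord <- order(di, seq_len(n))[seq_len(k)]
      idx[i, ] <- ord
      dst[i, ] <- sqrt(di[ord])
    }
  }
  list(index = idx, dist = dst)
}

#' Local standard deviation of the trajectory
#'
#' Population standard deviation of the pooled coordinates of the embedded
#' points in a temporal window of \code{window} frames centered on state t
#' (indices \code{t - floor(w/2) ... t + ceiling(w/2) - 1}), truncated at the
#' ends of the state's recording. This sets the local noise scale of the
#' asymmetric kernel.
#'
#' @param points an \linkS4class{EmbeddedSeries} or numeric matrix.
#' @param t state index (may be a vector).
#' @param window window length in frames (>= 2); default 12.
#' @return numeric vector of local SDs, one per \code{t}.
#' @export
localStd <- function(points, t, window = 12L) {
  stopifnot(window >= 2)
  pts <- if (is(points, "EmbeddedSeries")) points@points else as.matrix(points)
  recId <- if (is(points, "EmbeddedSeries")) points@recordingId
           else rep(1L, nrow(pts))
  n <- nrow(pts)
  firstIdx <- which(!duplicated(recId))
  lastIdx <- c(firstIdx[-1] - 1L, n)
  grp <- findInterval(seq_len(n), firstIdx)
  lo <- pmax(t - floor(window / 2), firstIdx[grp[t]])
  hi <- pmin(t + ceiling(window / 2) - 1L, lastIdx[grp[t]])
  vapply(seq_along(t), function(i) {
    x <- pts[lo[i]:hi[i], , drop = FALSE]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
}

#' Build the asymmetric diffusion transition matrix
#'
#' Casts the embedded trajectory into a sparse row-stochastic matrix M. Row t
#' places Gaussian kernel mass on the neighborhood of the *next* observed
#' point: \deqn{k_{FP}(D_t, D_j) = \exp(-\|D_{t+1} - D_j\|^2 / (2\sigma^2))}
#' over a neighborhood of \code{kNeighbors} points -- \eqn{D_{t+1}} itself
#' plus its \code{kNeighbors - 1} nearest neighbors -- then normalizes the
#' row to sum 1. \code{kNeighbors = 1} is thus the deterministic limit in
#' which the matrix exactly replays the observed sequence. Forward-centering makes M asymmetric and
#' lets its complex spectrum express the cyclic flux of the dynamics.
#'
#' The bandwidth couples the local trajectory scale to the kernel itself:
#' \eqn{\sigma^2 = \sigma_l(D_{t+1})\,\sigma_l(D_t)\,\langle k_{FP}\rangle},
#' where \eqn{\sigma_l} is \code{\link{localStd}} and the bracket averages the
#' kernel over the neighborhood (including \eqn{D_{t+1}}). Because the
#' definition is self-referential, it is resolved either by a deterministic
#' two-pass scheme (\code{sigmaMode = "two_pass"}: provisional kernel with
#' \eqn{\sigma_0^2 = \sigma_l(D_{t+1})\sigma_l(D_t)}, then one update) or by
#' damped fixed-point iteration (\code{"fixed_point"}, tolerance 1e-6, at
#' most 50 iterations). If \eqn{\sigma^2 = 0} for a row (locally constant
#' data) all mass falls on \eqn{D_{t+1}}, with a warning.
#'
#' The final state of each recording has no observed successor. With
#' \code{terminal = "absorb"} (default) it receives a self-loop, keeping M
#' exactly row-stochastic (largest-modulus eigenvalue exactly 1); with
#' \code{terminal = "drop"} its row is left empty (sub-stochastic M, used
#' when the deterministic sequence-reproduction limit is wanted in pure
#' form).
#'
#' @param points an \linkS4class{EmbeddedSeries}.
#' @param kNeighbors neighborhood size (default 12).
#' @param localWindow temporal window of \code{\link{localStd}} (default 12).
#' @param sigmaMode \code{"two_pass"} (default) or \code{"fixed_point"}.
#' @param terminal handling of recording-final states: \code{"absorb"} or
#'   \code{"drop"}.
#' @return a \linkS4class{TransitionMatrix}.
#' @examples
#' sim <- simulateNoisyLoops(nFrames = 300, nNeurons = 3, seed = 1)
#' pre <- preprocessRecording(sim$recording)
#' emb <- delayEmbed(pre$activity, pre$deriv, EmbedConfig(tau = 5, nDelays = 1))
#' M <- buildTransitionMatrix(emb, kNeighbors = 12)
#' range(Matrix::rowSums(transitionProbs(M)))
#' @export
buildTransitionMatrix <- function(points, kNeighbors = 12L, localWindow = 12L,
                                  sigmaMode = c("two_pass", "fixed_point"),
                                  terminal = c("absorb", "drop")) {
  stopifnot(is(points, "EmbeddedSeries"), kNeighbors >= 1, localWindow >= 2)
  sigmaMode <- match.arg(sigmaMode)
  terminal <- match.arg(terminal)
  pts <- points@points
  n <- nrow(pts)
  recId <- points@recordingId
  isLast <- c(recId[-n] != recId[-1], TRUE)       # final state of each recording
  if (kNeighbors >= n) stop("kNeighbors must be < number of points")
  # the successor D_{t+1} counts as the first neighborhood member, so the
  # neighborhood holds kNeighbors points total and k = 1 is the pure
  # deterministic (sequence-reproducing) limit
  nn <- if (kNeighbors > 1) nearestNeighbors(pts, kNeighbors - 1L) else NULL
  sl <- localStd(points, seq_len(n), localWindow)
  triplets <- vector("list", n)
  zeroSigma <- 0L
  for (t in which(!isLast)) {
    succ <- t + 1L
    nbr <- if (is.null(nn)) succ else c(succ, nn$index[succ, ])
    d2 <- if (is.null(nn)) 0 else c(0, nn$dist[succ, ])^2
    s0 <- sl[succ] * sl[t]
    if (s0 <= 0) {
      zeroSigma <- zeroSigma + 1L
      triplets[[t]] <- cbind(t, succ, 1)
      next
    }
    k0 <- exp(-d2 / (2 * s0))
    s2 <- s0 * mean(k0)
    if (sigmaMode == "fixed_point") {
      for (it in 1:50) {
        s2new <- s0 * mean(exp(-d2 / (2 * s2)))
        if (s2new <= 0) break
        if (abs(s2new - s2) < 1e-6 * s2) { s2 <- s2new; break }
        s2 <- s2new
      }
    }
    w <- exp(-d2 / (2 * s2))
    tot <- sum(w)
    if (!is.finite(tot) || tot <= 0) {
      triplets[[t]] <- cbind(t, succ, 1)
      next
    }
    triplets[[t]] <- cbind(t, nbr, w / tot)
  }
  if (zeroSigma > 0)
    warning(zeroSigma, " row(s) had sigma^2 = 0 (locally constant data); ",
            "all mass assigned to the observed successor")
  if (terminal == "absorb")
    for (t in which(isLast)) triplets[[t]] <- cbind(t, t, 1)
  tr <- do.call(rbind, triplets)
  M <- Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                            dims = c(n, n))
  new("TransitionMatrix", probs = M, frameIndex = points@frameIndex,
      recordingId = recId, terminal = which(isLast))
}

#' Propagate a state distribution through the transition matrix
#'
#' Evolves a probability distribution over states for t steps:
#' \eqn{x_t = x_0 M^t} (row-vector convention; mass is conserved because M is
#' row-stochastic).
#'
#' @param M a \linkS4class{TransitionMatrix} (or sparse/dense matrix).
#' @param x0 initial distribution over states (sums to 1).
#' @param t nonnegative integer number of steps.
#' @return numeric distribution after t steps.
#' @export
simulateStates <- function(M, x0, t) {
  P <- if (is(M, "TransitionMatrix")) M@probs else M
  if (t < 0) stop("t must be >= 0")
  stopifnot(length(x0) == nrow(P))
  if (abs(sum(x0) - 1) > 1e-9) stop("x0 must sum to 1")
  x <- x0
  for (i in seq_len(t)) x <- as.numeric(x %*% P)
  x
}
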