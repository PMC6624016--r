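#' Leading cyclic eigenmode of a transition matrix
#'
#' Among the eigenvalues of M with a genuinely nonzero imaginary part
#' (|Im| > 1e-8), returns the one of largest modulus together with a right
#' eigenvector. The member of the conjugate pair with positive imaginary part
#' is returned. A fully symmetric M has a purely real spectrum and raises the
#' error "no cyclic mode".
#'
#' For small matrices a dense LAPACK eigendecomposition is used; above
#' \code{denseLimit} states the leading part of the spectrum is computed by
#' deterministic orthogonal subspace iteration on the sparse matrix (real
#' Schur block, complex pairs recovered from the projected matrix), falling
#' back to the dense path if the iteration fails to converge.
#'
#' @param M a \linkS4class{TransitionMatrix} or square matrix.
#' @param denseLimit above this dimension use subspace iteration first
#'   (default 2500).
#' @param nev number of leading eigenpairs tracked iteratively (default 12).
#' @return list with complex \code{value} and complex \code{vector}.
#' @export
leadingCyclicMode <- function(M, denseLimit = 2500L, nev = 12L) {
  P <- if (is(M, "TransitionMatrix")) M@probs else M
  n <- nrow(P)
  pick <- function(vals, vecs) {
    cx <- which(abs(Im(vals)) > 1e-8)
    if (!length(cx)) stop("no cyclic mode: spectrum is real")
    best <- cx[which.max(Mod(vals[cx]))]
    lam <- vals[best]; v <- vecs[, best]
    if (Im(lam) < 0) { lam <- Conj(lam); v <- Conj(v) }
    list(value = lam, vector = v)
  }
  if (n > denseLimit) {
    it <- .subspaceEigs(P, nev = nev)
    if (!is.null(it)) {
      res <- tryCatch(pick(it$values, it$vectors), error = function(e) e)
      if (!inherits(res, "error")) return(res)
      if (grepl("no cyclic mode", conditionMessage(res))) stop(res)
    }
  }
  e <- eigen(as.matrix(P))
  pick(e$values, e$vectors)
}

# Merge clusters whose mutual per-frame transition rate exceeds mergeRate:
# arcs of one loop trade mass every revolution, disjoint loops only at rare
# junction hops.
.mergeFluxesByFlow <- function(P, labels, mergeRate = 0.02) {
  repeat {
    labs <- sort(unique(labels))
    K <- length(labs)
    if (K < 2) break
    S <- Matrix::sparseMatrix(i = seq_along(labels),
                              j = match(labels, labs), x = 1,
                              dims = c(length(labels), K))
    flow <- as.matrix(Matrix::t(S) %*% P %*% S)      # total mass a -> b
    size <- as.numeric(Matrix::colSums(S))
    rate <- flow / size                               # per-frame rate from a
    diag(rate) <- 0
    rate <- pmax(rate, t(rate))
    if (max(rate) <= mergeRate) break
    pair <- which(rate == max(rate), arr.ind = TRUE)[1, ]
    labels[labels == labs[max(pair)]] <- labs[min(pair)]
  }
  as.integer(factor(labels, levels = unique(labels)))
}

# Deterministic orthogonal (subspace) iteration for the leading eigenpairs of
# a sparse real matrix. Real arithmetic throughout; complex conjugate pairs
# emerge from the eigendecomposition of the small projected matrix. Returns
# NULL when the residuals fail to converge.
.subspaceEigs <- function(P, nev = 12L, block = NULL, maxIter = 400L,
                          tol = 1e-9) {
  n <- nrow(P)
  b <- if (is.null(block)) min(n, max(2L * nev, nev + 8L)) else block
  # fixed, RNG-free starting basis: smooth Fourier-like columns
  idx <- seq_len(n)
  Q0 <- vapply(seq_len(b), function(k)
    cos(pi * k * idx / n) + sin(pi * (k + 1) * idx / (n + 1)), numeric(n))
  Q <- qr.Q(qr(Q0))
  lastVals <- NULL
  for (iter in seq_len(maxIter)) {
    Z <- as.matrix(P %*% Q)
    Q <- qr.Q(qr(Z))
    if (iter %% 5 == 0 || iter == maxIter) {
      PQ <- as.matrix(P %*% Q)
      Tm <- crossprod(Q, PQ)
      ed <- eigen(Tm)
      ord <- order(Mod(ed$values), decreasing = TRUE)
      vals <- ed$values[ord]
      Y <- ed$vectors[, ord, drop = FALSE]
      kk <- min(nev, b)
      # explicit residuals ||P v - lambda v|| for the tracked pairs
      Vl <- Q %*% Y[, seq_len(kk), drop = FALSE]
      PV <- PQ %*% Y[, seq_len(kk), drop = FALSE]
      resid <- vapply(seq_len(kk), function(j)
        sqrt(sum(Mod(PV[, j] - vals[j] * Vl[, j])^2)), numeric(1))
      if (all(resid < tol * pmax(Mod(vals[seq_len(kk)]), 0.1)))
        return(list(values = vals[seq_len(kk)], vectors = Vl))
      lastVals <- vals
    }
  }
  NULL
}

#' Assign a phase to every state from the leading cyclic eigenvector
#'
#' The phase of state t is the componentwise argument
#' \eqn{\theta_t = \mathrm{atan2}(\mathrm{Im}\, v_t, \mathrm{Re}\, v_t)} of
#' the leading complex right eigenvector. The global rotation of the
#' eigenvector is arbitrary; the orientation (sign of flow) is fixed so that
#' the median circular per-step increment \eqn{\Delta\theta} along the
#' observed frame order is positive. Components with negligible magnitude
#' (|v_t| < 1e-12) get an undefined phase (NA) and are flagged.
#'
#' @param v complex eigenvector from \code{\link{leadingCyclicMode}}.
#' @param order optional integer ordering of states in time (default: the
#'   given order) used for the orientation rule.
#' @return numeric vector of phases in \eqn{(-\pi, \pi]} (NA where undefined),
#'   with attribute \code{"flipped"} indicating whether the conjugate
#'   orientation was taken.
#' @export
assignPhase <- function(v, order = seq_along(v)) {
  theta <- atan2(Im(v), Re(v))
  theta[Mod(v) < 1e-12] <- NA_real_
  th <- theta[order]
  dth <- diff(th)
  dth <- dth[!is.na(dth)]
  dth <- atan2(sin(dth), cos(dth))          # circular increments
  flipped <- FALSE
  if (length(dth) && stats::median(dth) < 0) {
    theta <- -theta
    flipped <- TRUE
  }
  # map any -pi to +pi so the range is (-pi, pi]
  theta[!is.na(theta) & theta <= -pi] <- pi
  attr(theta, "flipped") <- flipped
  theta
}

#' Densify a sparse transition matrix by exponentiation
#'
#' Returns \eqn{M^N} for the smallest N >= 1 such that every row has at least
#' \code{minFrac} of its entries nonzero, capping N at \code{maxExponent}
#' (with a warning; expected when M is reducible, e.g. multiple disjoint
#' fluxes). Exponentiation leaves the eigenvectors unchanged and maps
#' eigenvalues \eqn{\lambda \to \lambda^N}; it corresponds to letting the
#' system evolve N steps so rows describe diffusion-distance neighborhoods.
#'
#' @param M a \linkS4class{TransitionMatrix} or sparse matrix.
#' @param minFrac minimum fraction of nonzero entries per row (default 0.25).
#' @param maxExponent cap on N (default 64).
#' @param prune entries below this value are dropped after each
#'   multiplication to keep the matrix sparse (default 0, no pruning).
#' @return list with the densified \code{matrix} and the integer
#'   \code{exponent} N used.
#' @export
densify <- function(M, minFrac = 0.25, maxExponent = 64L, prune = 0) {
  P <- if (is(M, "TransitionMatrix")) M@probs else M
  stopifnot(minFrac > 0, minFrac <= 1)
  n <- nrow(P)
  need <- ceiling(minFrac * n)
  rowNnz <- function(A) {
    A <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
    tabulate(A@i[A@x != 0] + 1L, n)
  }
  Md <- P
  N <- 1L
  while (min(rowNnz(Md)) < need && N < maxExponent) {
    Md <- Md %*% P
    if (prune > 0) {
      Md@x[Md@x < prune] <- 0
      Md <- Matrix::drop0(Md)
    }
    N <- N + 1L
  }
  if (min(rowNnz(Md)) < need)
    warning("densification capped at N = ", maxExponent,
            " before reaching the requested row fill (reducible matrix?)")
  list(matrix = Md, exponent = N)
}

#' Maximum time-lagged correlation between rows
#'
#' For each pair of rows of the (densified) transition matrix, computes the
#' maximum Pearson correlation over all circular shifts of one row against
#' the other; rows belonging to the same coherent trajectory appear as
#' diagonal bands and reach high correlation at the lag equal to their
#' temporal offset. The result is symmetric with unit diagonal; pairs
#' involving a constant row get correlation 0.
#'
#' Computed via FFT cross-correlation, O(n^2 log n) overall.
#'
#' @param Md square numeric/sparse matrix (rows ordered by frame).
#' @return dense symmetric similarity matrix C with diagonal 1.
#' @export
laggedRowCorrelation <- function(Md) {
  A <- as.matrix(Md)
  n <- nrow(A)
  if (n != ncol(A)) stop("Md must be square")
  mu <- rowMeans(A)
  sdv <- sqrt(pmax(rowMeans(A^2) - mu^2, 0))   # population convention
  Z <- A - mu
  constRow <- sdv < 1e-15
  Ft <- t(stats::mvfft(t(Z)))                  # row-wise FFT: n x n complex
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # circular cross-correlation of row i with every row at all lags
    prod <- sweep(Ft, 2, Conj(Ft[i, ]), "*")
    cc <- Re(stats::mvfft(t(prod), inverse = TRUE)) / n   # n lags x n rows
    best <- apply(cc, 2, max) / n                         # max over lags
    C[i, ] <- best / (sdv[i] * sdv)
  }
  C[constRow, ] <- 0
  C[, constRow] <- 0
  C <- pmin(pmax((C + t(C)) / 2, -1), 1)
  C <- pmax(C, t(C))                           # symmetric max, numerically safe
  diag(C) <- 1
  C
}

#' Cluster states into fluxes by maximum modularity
#'
#' Builds a weighted undirected graph from the row-similarity matrix
#' (negative weights clipped to zero, diagonal ignored) and applies Louvain
#' maximum-modularity clustering (\code{igraph::cluster_louvain}), keeping
#' the best of \code{nRestarts} seeded restarts by modularity. Labels are
#' contiguous integers from 1, renumbered in order of first appearance along
#' the state sequence.
#'
#' @param C symmetric similarity matrix from
#'   \code{\link{laggedRowCorrelation}}.
#' @param nRestarts number of seeded restarts (default 10).
#' @param seed base RNG seed (default 1).
#' @return integer vector of flux labels (one per state).
#' @export
clusterFluxes <- function(C, nRestarts = 10L, seed = 1L) {
  C <- as.matrix(C)
  W <- pmax(C, 0)
  diag(W) <- 0
  if (all(W == 0)) return(rep(1L, nrow(C)))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  best <- NULL; bestQ <- -Inf
  for (r in seq_len(nRestarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g)
    q <- igraph::modularity(cl)
    if (q > bestQ) { bestQ <- q; best <- igraph::membership(cl) }
  }
  lab <- as.integer(best)
  # renumber contiguously in order of first appearance
  as.integer(factor(lab, levels = unique(lab)))
}

#' Full flux decomposition of a transition matrix
#'
#' Chains densification, time-lagged row correlation, modularity clustering,
#' and per-flux phase extraction: after clustering, the leading cyclic mode
#' and phases are recomputed within each flux's own (re-normalized)
#' submatrix, so every loop carries an internally coherent phase. With
#' \code{cluster = FALSE} all states form a single flux and the global
#' eigenmode supplies the phase.
#'
#' Modularity clustering over-partitions a single loop into phase arcs
#' (a known property of community detection on ring-like graphs), so
#' clusters that exchange probability mass faster than \code{mergeRate} per
#' frame are merged afterwards: a genuine pair of loops only communicates
#' through occasional junction hops (rates well below 0.01/frame), whereas
#' consecutive arcs of one loop trade mass every cycle.
#'
#' @param M a \linkS4class{TransitionMatrix}.
#' @param minFrac densification row-fill target (default 0.25).
#' @param cluster run flux clustering (default TRUE); set FALSE when the
#'   data are known to hold a single loop.
#' @param nRestarts,seed passed to \code{\link{clusterFluxes}}.
#' @param mergeRate per-frame inter-cluster transition rate above which two
#'   clusters are considered arcs of the same flux (default 0.02).
#' @return a \linkS4class{FluxDecomposition}.
#' @examples
#' sim <- simulateNoisyLoops(nFrames = 400, nNeurons = 3, seed = 1)
#' pre <- preprocessRecording(sim$recording)
#' emb <- delayEmbed(pre$activity, pre$deriv, EmbedConfig(tau = 5, nDelays = 2))
#' M <- buildTransitionMatrix(emb)
#' fd <- fluxDecompose(M, cluster = FALSE)
#' fd
#' @export
fluxDecompose <- function(M, minFrac = 0.25, cluster = TRUE,
                          nRestarts = 10L, seed = 1L, mergeRate = 0.02) {
  stopifnot(is(M, "TransitionMatrix"))
  n <- nrow(M@probs)
  # recording-final states have no observed successor; they are excluded from
  # densification/clustering (an absorbing self-loop would otherwise soak up
  # all mass under exponentiation) and inherit their predecessor's labels
  term <- M@terminal
  keep <- setdiff(seq_len(n), term)
  Pk <- M@probs[keep, keep, drop = FALSE]
  rs <- Matrix::rowSums(Pk)
  degenerate <- which(rs == 0)   # all mass went to a terminal column
  rs[degenerate] <- 1
  Pk <- Matrix::Diagonal(x = 1 / rs) %*% Pk
  if (length(degenerate))
    Pk <- Pk + Matrix::sparseMatrix(i = degenerate, j = degenerate, x = 1,
                                    dims = dim(Pk))
  if (cluster) {
    dn <- densify(Pk, minFrac = minFrac)
    C <- laggedRowCorrelation(dn$matrix)
    alphaK <- clusterFluxes(C, nRestarts = nRestarts, seed = seed)
    alphaK <- .mergeFluxesByFlow(Pk, alphaK, mergeRate)
    expo <- dn$exponent
  } else {
    alphaK <- rep(1L, length(keep))
    expo <- 1L
  }
  alpha <- integer(n)
  alpha[keep] <- alphaK
  for (t in term) alpha[t] <- if (t > 1) alpha[t - 1L] else 1L
  theta <- rep(NA_real_, n)
  leadVal <- NA_complex_; leadVec <- complex(n)
  for (a in sort(unique(alpha))) {
    sel <- which(alpha == a)
    if (length(sel) < 3) { theta[sel] <- 0; next }
    sub <- M@probs[sel, sel, drop = FALSE]
    rs <- Matrix::rowSums(sub)
    empty <- rs == 0
    if (any(empty)) {           # states whose successors left the flux: absorb
      sub <- sub + Matrix::sparseMatrix(i = which(empty), j = which(empty),
                                        x = 1, dims = dim(sub))
      rs[empty] <- 1
    }
    sub <- Matrix::Diagonal(x = 1 / rs) %*% sub
    mode <- tryCatch(leadingCyclicMode(sub), error = function(e) NULL)
    if (is.null(mode)) { theta[sel] <- 0; next }
    theta[sel] <- assignPhase(mode$vector)
    if (is.na(Mod(leadVal)) || Mod(mode$value) > Mod(leadVal)) {
      leadVal <- mode$value
      leadVec[sel] <- mode$vector
    }
  }
  new("FluxDecomposition", theta = theta, alpha = alpha,
      leadEigenvalue = leadVal, leadEigenvector = leadVec,
      densifyExponent = as.integer(expo))
}
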