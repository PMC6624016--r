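#' Define Gaussian phase bins per flux
#'
#' For each flux \eqn{\alpha}, lays \code{ceiling(2*pi/deltaTheta)} Gaussian
#' bins with centers uniformly spaced over \eqn{(-\pi, \pi]} and width
#' (SD) \code{deltaTheta}. Empty bins are retained and only flagged after
#' summarization.
#'
#' @param decomp a \linkS4class{FluxDecomposition} (or an integer vector of
#'   flux labels).
#' @param deltaTheta phase bin spacing in radians (default 0.05).
#' @return data.frame with columns \code{alpha}, \code{thetaCenter},
#'   \code{thetaSd}.
#' @examples
#' nrow(makeBins(rep(1:2, 5), deltaTheta = 0.05))  # 126 per flux
#' @export
makeBins <- function(decomp, deltaTheta = 0.05) {
  stopifnot(deltaTheta > 0)
  alpha <- if (is(decomp, "FluxDecomposition")) decomp@alpha else
    as.integer(decomp)
  nb <- ceiling(2 * pi / deltaTheta)
  centers <- -pi + (seq_len(nb) - 0.5) * (2 * pi / nb)
  do.call(rbind, lapply(sort(unique(alpha)), function(a)
    data.frame(alpha = a, thetaCenter = centers, thetaSd = deltaTheta)))
}

#' Assign a phase to its most likely bin
#'
#' Among the bins of the same flux, picks the one maximizing the circular
#' Gaussian likelihood of \eqn{\theta} -- equivalently, the bin whose center
#' is nearest in circular distance (bins share one SD). Ties break to the
#' lower bin index.
#'
#' @param theta phase(s) in radians.
#' @param alpha flux label(s), recycled against theta.
#' @param bins bin table from \code{\link{makeBins}}.
#' @return integer bin index (row of \code{bins}) per input phase; NA phases
#'   give NA.
#' @export
assignBin <- function(theta, alpha, bins) {
  alpha <- rep_len(alpha, length(theta))
  out <- rep(NA_integer_, length(theta))
  for (a in unique(alpha)) {
    rows <- which(bins$alpha == a)
    if (!length(rows)) stop("no bins defined for flux ", a)
    sel <- which(alpha == a & !is.na(theta))
    if (!length(sel)) next
    d <- abs(outer(theta[sel], bins$thetaCenter[rows], "-"))
    d <- pmin(d, 2 * pi - d)                   # circular distance
    out[sel] <- rows[max.col(-d, ties.method = "first")]
  }
  out
}

#' Fit a manifold model from a flux decomposition
#'
#' Bins every state into its (theta, alpha) phase bin and fills the per-bin
#' summaries: mean delay-embedded activity, mean raw-neuron activity at lag 0
#' (over *all* recorded neurons, including any excluded from distance
#' computations), the per-bin behavioral-state distribution, occupancy, and
#' the empirical bin-level row-stochastic transition matrix (transitions
#' counted in frame order, never across recording boundaries). Bins with
#' fewer than \code{minCount} observations are flagged unassigned; their
#' summaries are retained but their modal behavior reads "unassigned".
#'
#' @param embedded an \linkS4class{EmbeddedSeries} of the training states.
#' @param decomp the matching \linkS4class{FluxDecomposition}.
#' @param behaviors optional per-state behavior labels (aligned to embedded
#'   points).
#' @param rawActivity optional matrix of per-state raw-neuron snapshots
#'   (rows aligned to embedded points; defaults to the lag-0 activity slice
#'   of the embedding).
#' @param deltaTheta phase bin spacing in radians (default 0.05).
#' @param minCount minimum occupancy before a bin is considered assigned
#'   (default 5).
#' @param preprocess list of preprocessing parameters to store (for
#'   projection of new recordings).
#' @param seed integer seed stored for reproducibility.
#' @return a \linkS4class{ManifoldModel}.
#' @export
buildManifold <- function(embedded, decomp, behaviors = NULL,
                          rawActivity = NULL, deltaTheta = 0.05,
                          minCount = 5L, preprocess = list(sigmaFrames = 1),
                          seed = 1L) {
  stopifnot(is(embedded, "EmbeddedSeries"), is(decomp, "FluxDecomposition"))
  pts <- embedded@points
  n <- nrow(pts)
  if (length(decomp@theta) != n)
    stop("decomposition and embedding disagree on the number of states")
  nNeu <- length(embedded@neurons)
  if (is.null(rawActivity))
    rawActivity <- pts[, seq_len(nNeu), drop = FALSE]  # lag-0 activity slice
  allNeurons <- colnames(rawActivity)
  if (is.null(allNeurons)) allNeurons <- embedded@neurons
  bins <- makeBins(decomp, deltaTheta)
  assign <- assignBin(decomp@theta, decomp@alpha, bins)
  nb <- nrow(bins)
  occ <- tabulate(assign, nb)
  ok <- !is.na(assign)
  grp <- function(m) {
    out <- matrix(0, nb, ncol(m))
    s <- rowsum(m[ok, , drop = FALSE], assign[ok], reorder = FALSE)
    out[as.integer(rownames(s)), ] <- s / pmax(occ[as.integer(rownames(s))], 1)
    out
  }
  meanEmb <- grp(pts)
  meanAct <- grp(as.matrix(rawActivity))
  colnames(meanAct) <- allNeurons
  if (!is.null(behaviors)) {
    stopifnot(length(behaviors) == n)
    lev <- sort(unique(as.character(behaviors)))
    bp <- matrix(0, nb, length(lev), dimnames = list(NULL, lev))
    tab <- table(factor(assign, levels = seq_len(nb)),
                 factor(behaviors, levels = lev))
    bp[] <- as.matrix(tab)
    bp[occ > 0, ] <- bp[occ > 0, , drop = FALSE] / occ[occ > 0]
  } else {
    lev <- character(0)
    bp <- matrix(0, nb, 0)
  }
  bins$occupancy <- occ
  bins$unassigned <- occ < minCount
  bins$modalBehavior <- if (length(lev)) {
    mb <- lev[max.col(bp, ties.method = "first")]
    mb[bins$unassigned | occ == 0] <- "unassigned"
    mb
  } else rep(NA_character_, nb)
  bt <- binTransitionCounts(assign, embedded@recordingId, nb)
  new("ManifoldModel", bins = bins, meanEmbedded = meanEmb,
      meanActivity = meanAct, behaviorProb = bp, behaviorLevels = lev,
      binTrans = bt, modelNeurons = embedded@neurons,
      allNeurons = allNeurons, config = embedded@config,
      preprocess = preprocess, assignments = assign,
      trainActivity = as.matrix(rawActivity),
      trainRecordingId = embedded@recordingId, seed = as.integer(seed))
}

#' Empirical bin-level transition matrix
#'
#' Counts transitions between consecutive bin assignments (in frame order,
#' within each recording) and row-normalizes. Bins never visited keep an
#' all-zero row.
#'
#' @param assign integer bin assignment per state, frame-ordered.
#' @param recordingId integer recording id per state (no transition is
#'   counted across a change of id); default: a single recording.
#' @param nBins total number of bins (default \code{max(assign)}).
#' @return sparse row-stochastic matrix (bins x bins).
#' @export
binTransitionCounts <- function(assign, recordingId = rep(1L, length(assign)),
                                nBins = max(assign, na.rm = TRUE)) {
  from <- assign[-length(assign)]
  to <- assign[-1]
  keep <- recordingId[-length(assign)] == recordingId[-1] &
    !is.na(from) & !is.na(to)
  from <- from[keep]; to <- to[keep]
  M <- Matrix::sparseMatrix(i = from, j = to, x = 1,
                            dims = c(nBins, nBins), repr = "C")
  rs <- Matrix::rowSums(M)
  nz <- rs > 0
  M[nz, ] <- M[nz, , drop = FALSE] / rs[nz]
  methods::as(M, "CsparseMatrix")
}

#' Project a new recording onto an existing manifold
#'
#' Preprocesses and delay-embeds a new (possibly neuron-incomplete)
#' recording with the model's stored configuration, then assigns every
#' embedded point to the bin whose mean embedded activity is nearest in
#' Euclidean distance restricted to the coordinates of the neurons actually
#' available -- the mechanism that lets recordings sharing only a subset of
#' neurons with the model be decoded.
#'
#' @param model a \linkS4class{ManifoldModel}.
#' @param rec a \linkS4class{Recording} whose neuron names overlap
#'   \code{model@modelNeurons}.
#' @param availableNeurons neurons to use (default: all shared neurons).
#' @return list with integer \code{bin} per embedded frame, the embedded
#'   \code{frameIndex}, and the predicted modal \code{behavior} per frame
#'   (when the model carries behavior distributions).
#' @export
projectRecording <- function(model, rec,
                             availableNeurons = intersect(neuronNames(rec),
                                                          model@modelNeurons)) {
  stopifnot(is(model, "ManifoldModel"), is(rec, "Recording"))
  if (length(availableNeurons) < 1)
    stop("no shared neurons between the recording and the model")
  if (!all(availableNeurons %in% model@modelNeurons))
    stop("availableNeurons must be a subset of the model's neurons")
  if (!all(availableNeurons %in% neuronNames(rec)))
    stop("recording lacks requested neurons: ",
         paste(setdiff(availableNeurons, neuronNames(rec)), collapse = ", "))
  pre <- preprocessRecording(rec, model@preprocess$sigmaFrames %||% 1)
  emb <- delayEmbed(pre$activity, pre$deriv, model@config)
  # coordinate positions of the available neurons in the model's layout
  nNeu <- length(model@modelNeurons)
  nd <- model@config@nDelays
  slotIdx <- match(availableNeurons, model@modelNeurons)
  coordIdx <- as.vector(outer(slotIdx, (0:(2 * (nd + 1) - 1)) * nNeu, "+"))
  # matching columns in the new embedding (its own neuron order)
  newIdx <- match(availableNeurons, neuronNames(rec))
  nNew <- length(neuronNames(rec))
  newCoordIdx <- as.vector(outer(newIdx, (0:(2 * (nd + 1) - 1)) * nNew, "+"))
  X <- emb@points[, newCoordIdx, drop = FALSE]
  B <- model@meanEmbedded[, coordIdx, drop = FALSE]
  occupied <- which(model@bins$occupancy > 0)
  d2 <- sweep(-2 * tcrossprod(X, B[occupied, , drop = FALSE]), 2,
              rowSums(B[occupied, , drop = FALSE]^2), "+")
  bin <- occupied[max.col(-d2, ties.method = "first")]
  behavior <- if (length(model@behaviorLevels))
    model@bins$modalBehavior[bin] else NULL
  list(bin = bin, frameIndex = emb@frameIndex, behavior = behavior)
}

#' Principal-axes coordinates of the manifold for visualization
#'
#' Orders the occupied bins by flux and phase, Gaussian-smooths the per-bin
#' mean activity circularly over phase (SD \code{2 * deltaTheta} by default),
#' and projects onto the first three principal components. Export-only
#' convenience; plays no role in simulation or decoding.
#'
#' @param model a \linkS4class{ManifoldModel}.
#' @param smoothSdBins smoothing SD expressed in bins (default 2).
#' @return data.frame with bin index, alpha, thetaCenter and coordinates
#'   PC1..PC3.
#' @export
dpcaCoordinates <- function(model, smoothSdBins = 2) {
  keep <- which(model@bins$occupancy > 0)
  if (length(keep) < 3) stop("need at least 3 occupied bins")
  ord <- keep[order(model@bins$alpha[keep], model@bins$thetaCenter[keep])]
  A <- model@meanActivity[ord, , drop = FALSE]
  # circular Gaussian smoothing within each flux
  sm <- A
  alph <- model@bins$alpha[ord]
  for (a in unique(alph)) {
    rows <- which(alph == a)
    m <- length(rows)
    if (m < 3) next
    off <- seq(-m %/% 2, m %/% 2)
    w <- stats::dnorm(off, sd = smoothSdBins)
    w <- w / sum(w)
    for (jj in seq_len(ncol(A))) {
      x <- A[rows, jj]
      sm[rows, jj] <- vapply(seq_len(m), function(i)
        sum(w * x[((i - 1 + off) %% m) + 1]), numeric(1))
    }
  }
  p <- stats::prcomp(sm, center = TRUE, scale. = FALSE)
  k <- min(3, ncol(p$x))
  out <- data.frame(bin = ord, alpha = alph,
                    thetaCenter = model@bins$thetaCenter[ord])
  for (i in seq_len(k)) out[[paste0("PC", i)]] <- p$x[, i]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
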