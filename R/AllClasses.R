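#' @include AllGenerics.R
NULL

#' Recording: a multivariate activity time series
#'
#' A \code{Recording} holds a frames x neurons matrix of activity (e.g.
#' z-scored \eqn{\Delta F/F} calcium traces), per-frame behavioral labels
#' (optional), the acquisition frame rate, and an animal identifier. It
#' extends \linkS4class{SummarizedExperiment}: the assay is stored neurons x
#' frames (features x samples), behavior lives in \code{colData}, and
#' \code{frame_rate} / \code{animal_id} in \code{metadata}.
#'
#' @param activity numeric matrix, frames x neurons.
#' @param neuronNames character vector of unique neuron identifiers; defaults
#'   to \code{colnames(activity)}.
#' @param frameRate acquisition rate in frames per second (default 3, typical
#'   of whole-brain calcium imaging).
#' @param behavior optional character/factor vector of per-frame behavioral
#'   labels, length \code{nrow(activity)}.
#' @param animalId identifier of the recorded individual.
#' @param x a \code{Recording}.
#'
#' @return \code{Recording()} returns a \code{Recording} object.
#'   \code{activity()} returns the frames x neurons matrix; \code{neuronNames},
#'   \code{nFrames}, \code{frameRate}, \code{animalId} and
#'   \code{behaviorLabels} return the corresponding fields
#'   (\code{behaviorLabels} returns \code{NULL} when no labels are attached).
#'
#' @examples
#' rec <- Recording(matrix(rnorm(60), 30, 2),
#'                  neuronNames = c("AVAL", "RIML"))
#' nFrames(rec)
#' head(activity(rec))
#' @aliases activity neuronNames nFrames frameRate animalId behaviorLabels
#' @export
setClass("Recording", contains = "SummarizedExperiment")

#' @rdname Recording
#' @export
Recording <- function(activity, neuronNames = colnames(activity),
                      frameRate = 3, behavior = NULL, animalId = "animal_1") {
  activity <- as.matrix(activity)
  if (is.null(neuronNames))
    neuronNames <- paste0("n", seq_len(ncol(activity)))
  if (length(neuronNames) != ncol(activity))
    stop("neuronNames length must match the number of columns of activity")
  cd <- S4Vectors::DataFrame(row.names = seq_len(nrow(activity)))
  if (!is.null(behavior)) {
    if (length(behavior) != nrow(activity))
      stop("behavior must have one label per frame (",
           nrow(activity), " frames, got ", length(behavior), " labels)")
    cd$behavior <- as.character(behavior)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = t(unname(activity))),
    colData = cd)
  rownames(se) <- neuronNames
  S4Vectors::metadata(se) <- list(frame_rate = frameRate, animal_id = animalId)
  new("Recording", se)
}

setValidity("Recording", function(object) {
  nm <- rownames(object)
  if (is.null(nm) || anyDuplicated(nm))
    return("neuron names must be present and unique")
  if (any(!is.finite(SummarizedExperiment::assay(object))))
    return("activity contains non-finite values")
  TRUE
})

#' @rdname Recording
#' @export
setMethod("activity", "Recording", function(x) {
  m <- t(SummarizedExperiment::assay(x, "activity"))
  dimnames(m) <- list(NULL, rownames(x))
  m
})

#' @rdname Recording
#' @export
setMethod("neuronNames", "Recording", function(x) rownames(x))

#' @rdname Recording
#' @export
setMethod("nFrames", "Recording", function(x) ncol(x))

#' @rdname Recording
#' @export
setMethod("frameRate", "Recording", function(x) S4Vectors::metadata(x)$frame_rate)

#' @rdname Recording
#' @export
setMethod("animalId", "Recording", function(x) S4Vectors::metadata(x)$animal_id)

#' @rdname Recording
#' @export
setMethod("behaviorLabels", "Recording", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("behavior" %in% colnames(cd)) as.character(cd$behavior) else NULL
})

setMethod("show", "Recording", function(object) {
  cat("Recording '", animalId(object), "': ", ncol(object), " frames x ",
      nrow(object), " neurons @ ", frameRate(object), " fps",
      if (!is.null(behaviorLabels(object))) " (+behavior)", "\n", sep = "")
  cat("  neurons:", paste(head(rownames(object), 6), collapse = ", "),
      if (nrow(object) > 6) "...", "\n")
})

#' EmbedConfig: delay-embedding parameters
#'
#' Holds the delay \code{tau} (frames) and the number of additional lags
#' \code{nDelays} beyond lag 0. The embedded dimension for n neurons is
#' \code{2 * n * (nDelays + 1)} (activity plus derivative at each lag).
#'
#' @param tau delay in frames (>= 1); default 10.
#' @param nDelays number of additional delays beyond lag zero (>= 0);
#'   default 5.
#' @return an \code{EmbedConfig} object.
#' @examples
#' EmbedConfig(tau = 10, nDelays = 5)
#' @export
setClass("EmbedConfig", representation(tau = "integer", nDelays = "integer"))

#' @rdname EmbedConfig
#' @export
EmbedConfig <- function(tau = 10L, nDelays = 5L) {
  new("EmbedConfig", tau = as.integer(tau), nDelays = as.integer(nDelays))
}

setValidity("EmbedConfig", function(object) {
  if (length(object@tau) != 1 || object@tau < 1L) return("tau must be >= 1")
  if (length(object@nDelays) != 1 || object@nDelays < 0L)
    return("nDelays must be >= 0")
  TRUE
})

setMethod("show", "EmbedConfig", function(object) {
  cat("EmbedConfig: tau =", object@tau, "frames,", object@nDelays, "delays\n")
})

#' EmbeddedSeries: delay-embedded phase-space points
#'
#' Rows of \code{points} are the delay-embedded state vectors
#' \eqn{D_t}; \code{frameIndex} maps each point back to its original frame
#' (1-based, strictly increasing within a recording) and \code{recordingId}
#' identifies the source recording so that no transition spans a recording
#' boundary. Coordinate layout: activity at lags \code{0, tau, ..,
#' nDelays*tau} (each slice in \code{neuron} order), then derivative slices at
#' the same lags.
#'
#' @param x an \code{EmbeddedSeries}.
#' @return \code{embeddedPoints()} returns the points matrix; \code{frameIndex()}
#'   the original frame of each point.
#' @aliases embeddedPoints frameIndex
#' @export
setClass("EmbeddedSeries", representation(
  points = "matrix", frameIndex = "integer", recordingId = "integer",
  neurons = "character", config = "EmbedConfig"))

setValidity("EmbeddedSeries", function(object) {
  n <- nrow(object@points)
  if (length(object@frameIndex) != n || length(object@recordingId) != n)
    return("frameIndex and recordingId must have one entry per point")
  d <- 2L * length(object@neurons) * (object@config@nDelays + 1L)
  if (ncol(object@points) != d)
    return(sprintf("dimension %d does not match 2*neurons*(nDelays+1) = %d",
                   ncol(object@points), d))
  spl <- split(object@frameIndex, object@recordingId)
  if (!all(vapply(spl, function(f) all(diff(f) > 0), logical(1))))
    return("frameIndex must be strictly increasing within each recording")
  TRUE
})

#' @rdname EmbeddedSeries
#' @export
setMethod("embeddedPoints", "EmbeddedSeries", function(x) x@points)

#' @rdname EmbeddedSeries
#' @export
setMethod("frameIndex", "EmbeddedSeries", function(x) x@frameIndex)

setMethod("show", "EmbeddedSeries", function(object) {
  cat("EmbeddedSeries:", nrow(object@points), "points x",
      ncol(object@points), "dims (", length(object@neurons), "neurons, tau =",
      object@config@tau, ",", object@config@nDelays, "delays )\n")
})

#' TransitionMatrix: empirical row-stochastic dynamics
#'
#' Sparse row-stochastic matrix over observed states. Row t carries the
#' transition probabilities from state t, concentrated on the neighborhood of
#' the next observed state. States that end a recording have no successor and
#' are dropped from the state set.
#'
#' @param x a \code{TransitionMatrix}.
#' @return \code{transitionProbs()} returns the sparse probability matrix.
#' @aliases transitionProbs
#' @export
setClass("TransitionMatrix", representation(
  probs = "sparseMatrix", frameIndex = "integer", recordingId = "integer",
  terminal = "integer"))

setValidity("TransitionMatrix", function(object) {
  p <- object@probs
  if (nrow(p) != ncol(p)) return("probs must be square")
  if (length(object@frameIndex) != nrow(p))
    return("frameIndex must map every state")
  if (any(p@x < 0)) return("probabilities must be nonnegative")
  rs <- Matrix::rowSums(p)
  if (any(abs(rs - 1) > 1e-9 & rs != 0))
    return("every row must sum to 1 (within 1e-9) or be empty (terminal)")
  TRUE
})

#' @rdname TransitionMatrix
#' @export
setMethod("transitionProbs", "TransitionMatrix", function(x) x@probs)

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix:", nrow(object@probs), "states,",
      Matrix::nnzero(object@probs), "nonzero transitions\n")
})

#' FluxDecomposition: phase and loop identity per state
#'
#' Assigns each state a phase \eqn{\theta \in (-\pi, \pi]} along its cyclic
#' flux (from the leading complex eigenmode of the transition matrix) and an
#' integer flux label \eqn{\alpha} (from maximum-modularity clustering of
#' time-lagged row correlations of the densified matrix). Flux labels are
#' contiguous integers starting at 1.
#'
#' @param x a \code{FluxDecomposition}.
#' @return \code{statePhase()} returns the per-state phase in radians;
#'   \code{fluxLabels()} the per-state integer loop label.
#' @aliases statePhase fluxLabels
#' @export
setClass("FluxDecomposition", representation(
  theta = "numeric", alpha = "integer", leadEigenvalue = "complex",
  leadEigenvector = "complex", densifyExponent = "integer"))

setValidity("FluxDecomposition", function(object) {
  if (length(object@theta) != length(object@alpha))
    return("theta and alpha must have equal length")
  ok <- is.finite(object@theta)
  if (any(object@theta[ok] <= -pi - 1e-12 | object@theta[ok] > pi + 1e-12))
    return("theta must lie in (-pi, pi]")
  if (length(object@alpha) &&
      !identical(sort(unique(object@alpha)), seq_len(max(object@alpha))))
    return("alpha labels must be contiguous from 1")
  if (length(object@leadEigenvalue) == 1 &&
      Mod(object@leadEigenvalue) > 1 + 1e-6)
    return("leading eigenvalue modulus must be <= 1 + 1e-6")
  TRUE
})

#' @rdname FluxDecomposition
#' @export
setMethod("statePhase", "FluxDecomposition", function(x) x@theta)

#' @rdname FluxDecomposition
#' @export
setMethod("fluxLabels", "FluxDecomposition", function(x) x@alpha)

setMethod("show", "FluxDecomposition", function(object) {
  cat("FluxDecomposition:", length(object@theta), "states,",
      max(c(object@alpha, 0L)), "flux(es); |lambda| =",
      signif(Mod(object@leadEigenvalue), 4), "\n")
})

#' ManifoldModel: the (theta, alpha) manifold
#'
#' The fitted manifold: per-bin phase centers and flux labels, per-bin mean
#' embedded activity, per-bin mean raw-neuron activity (all recorded neurons,
#' including any excluded from distance computations), behavioral-state
#' distributions, occupancies, and the bin-level row-stochastic transition
#' matrix. Training-state assignments and raw activity snapshots are retained
#' so that simulated paths can be mapped back to activity either by bin means
#' or by sampling stored member snapshots.
#'
#' @param x a \code{ManifoldModel}.
#' @return \code{binInfo()} returns the bin table (alpha, thetaCenter,
#'   thetaSd, occupancy, unassigned flag, modal behavior); \code{nBins()} the
#'   number of bins; \code{binTransitions()} the sparse bin-level transition
#'   matrix; \code{behaviorDist()} the bins x behaviors probability matrix.
#' @aliases binInfo nBins binTransitions behaviorDist
#' @export
setClass("ManifoldModel", representation(
  bins = "data.frame",            # alpha, thetaCenter, thetaSd, occupancy, unassigned
  meanEmbedded = "matrix",        # bins x d
  meanActivity = "matrix",        # bins x all neurons
  behaviorProb = "matrix",        # bins x behavior levels
  behaviorLevels = "character",
  binTrans = "sparseMatrix",      # bins x bins, row-stochastic over visited bins
  modelNeurons = "character",     # neurons used for distances
  allNeurons = "character",       # neurons reconstructed in meanActivity
  config = "EmbedConfig",
  preprocess = "list",            # smoothing sigma etc.
  assignments = "integer",        # training state -> bin
  trainActivity = "matrix",       # training frames x all neurons (lag-0 snapshots)
  trainRecordingId = "integer",
  seed = "integer"))

setValidity("ManifoldModel", function(object) {
  nb <- nrow(object@bins)
  if (nrow(object@meanEmbedded) != nb || nrow(object@behaviorProb) != nb ||
      nrow(object@meanActivity) != nb)
    return("per-bin summaries must have one row per bin")
  occ <- object@bins$occupancy
  if (sum(occ) != sum(!is.na(object@assignments)))
    return("occupancy totals must equal the number of assigned states")
  bp <- object@behaviorProb
  if (ncol(bp) > 0) {
    rs <- rowSums(bp)
    bad <- occ > 0 & abs(rs - 1) > 1e-9
    if (any(bad)) return("behavior distributions must sum to 1 where occupied")
  }
  if (nrow(object@binTrans) > 0) {
    rs <- Matrix::rowSums(object@binTrans)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      return("bin transition rows must sum to 1")
  }
  TRUE
})

#' @rdname ManifoldModel
#' @export
setMethod("binInfo", "ManifoldModel", function(x) x@bins)

#' @rdname ManifoldModel
#' @export
setMethod("nBins", "ManifoldModel", function(x) nrow(x@bins))

#' @rdname ManifoldModel
#' @export
setMethod("binTransitions", "ManifoldModel", function(x) x@binTrans)

#' @rdname ManifoldModel
#' @export
setMethod("behaviorDist", "ManifoldModel", function(x) x@behaviorProb)

setMethod("show", "ManifoldModel", function(object) {
  cat("ManifoldModel:", nrow(object@bins), "bins,",
      max(c(object@bins$alpha, 0L)), "flux(es),",
      length(object@modelNeurons), "model neurons;",
      sum(object@bins$occupancy), "training states\n")
  if (length(object@behaviorLevels))
    cat("  behaviors:", paste(object@behaviorLevels, collapse = ", "), "\n")
})
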