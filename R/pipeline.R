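#' Fit the full manifold pipeline on one or more recordings
#'
#' End-to-end orchestration: smooth, z-score and differentiate each
#' recording; delay-embed each independently and concatenate (no transition
#' ever spans a recording boundary); build the asymmetric diffusion
#' transition matrix; decompose into fluxes and phases; and bin into a
#' \linkS4class{ManifoldModel} with per-bin activity, behavior, occupancy
#' and transition summaries.
#'
#' Only the intersection of neuron names across recordings enters the
#' distance computations; \code{excludeNeurons} removes further channels
#' from the distances while keeping them in the activity reconstruction
#' (per-bin \code{meanActivity}), so an excluded neuron's expected activity
#' can still be read off the manifold.
#'
#' @param recordings list of \linkS4class{Recording}s (behavior labels are
#'   taken from each recording when present).
#' @param sigmaFrames Gaussian smoothing SD (default 1 frame).
#' @param tau embedding delay (default 10 frames).
#' @param nDelays number of additional delays (default 5).
#' @param kNeighbors kernel neighborhood size (default 12).
#' @param localWindow local-SD window (default 12 frames).
#' @param sigmaMode bandwidth resolution mode (default "two_pass").
#' @param minFrac densification row-fill target (default 0.25).
#' @param cluster run flux clustering (default TRUE).
#' @param deltaTheta phase bin spacing (default 0.05 rad).
#' @param minCount minimum bin occupancy (default 5).
#' @param excludeNeurons names removed from distance computations.
#' @param seed integer seed controlling clustering restarts.
#' @param verbose print stage progress to stderr.
#' @return a \linkS4class{ManifoldModel}.
#' @examples
#' sims <- lapply(1:2, function(s) simulateMarkovSwitcher(
#'   c(0.9, 0.9), list(c(1, 0, 0.5), c(0, 1, 0.2)), noiseSd = 0.1,
#'   nFrames = 600, seed = s, stateNames = c("forward", "backward")))
#' model <- fitPipeline(lapply(sims, `[[`, "recording"),
#'   tau = 3, nDelays = 2, deltaTheta = 0.3, cluster = FALSE)
#' model
#' @export
fitPipeline <- function(recordings, sigmaFrames = 1, tau = 10L, nDelays = 5L,
                        kNeighbors = 12L, localWindow = 12L,
                        sigmaMode = "two_pass", minFrac = 0.25,
                        cluster = TRUE, deltaTheta = 0.05, minCount = 5L,
                        excludeNeurons = character(0), seed = 1L,
                        verbose = FALSE) {
  if (is(recordings, "Recording")) recordings <- list(recordings)
  stopifnot(length(recordings) >= 1,
            all(vapply(recordings, is, logical(1), "Recording")))
  say <- function(...) if (verbose) message("[fluxmap] ", ...)
  shared <- Reduce(intersect, lapply(recordings, neuronNames))
  allNeurons <- shared                       # reconstruction keeps exclusions
  modelNeurons <- setdiff(shared, excludeNeurons)
  if (!length(modelNeurons))
    stop("no shared neurons left after exclusion")
  say("shared neurons: ", length(shared), "; model neurons: ",
      length(modelNeurons))
  cfg <- EmbedConfig(tau, nDelays)
  embs <- vector("list", length(recordings))
  rawRows <- vector("list", length(recordings))
  behRows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    pre <- preprocessRecording(rec, sigmaFrames)
    zAll <- activity(pre$activity)[, allNeurons, drop = FALSE]
    actModel <- .subsetRecording(pre$activity, modelNeurons)
    derModel <- .subsetRecording(pre$deriv, modelNeurons)
    emb <- delayEmbed(actModel, derModel, cfg, recordingId = i)
    embs[[i]] <- emb
    rawRows[[i]] <- zAll[emb@frameIndex, , drop = FALSE]
    beh <- behaviorLabels(rec)
    behRows[[i]] <- if (is.null(beh)) NULL else beh[emb@frameIndex]
  }
  embedded <- bindEmbedded(embs)
  say("embedded ", nrow(embedded@points), " states in ",
      ncol(embedded@points), " dimensions")
  M <- buildTransitionMatrix(embedded, kNeighbors = kNeighbors,
                             localWindow = localWindow,
                             sigmaMode = sigmaMode)
  say("transition matrix built")
  decomp <- fluxDecompose(M, minFrac = minFrac, cluster = cluster,
                          seed = seed)
  say("flux decomposition: ", max(decomp@alpha), " flux(es)")
  behaviors <- if (all(!vapply(behRows, is.null, logical(1))))
    do.call(c, behRows) else NULL
  model <- buildManifold(embedded, decomp, behaviors = behaviors,
                         rawActivity = do.call(rbind, rawRows),
                         deltaTheta = deltaTheta, minCount = minCount,
                         preprocess = list(sigmaFrames = sigmaFrames),
                         seed = seed)
  say("manifold: ", sum(model@bins$occupancy > 0), " occupied bins")
  model
}

# restrict a Recording to a neuron subset, preserving order given
.subsetRecording <- function(rec, neurons) {
  Recording(activity(rec)[, neurons, drop = FALSE], neuronNames = neurons,
            frameRate = frameRate(rec), behavior = behaviorLabels(rec),
            animalId = animalId(rec))
}
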